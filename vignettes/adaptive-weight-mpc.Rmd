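---
title: "Adaptive Akaike-weighted multiple-model predictive control of signaling dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Akaike-weighted multiple-model predictive control of signaling dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awmpc)
```

## The problem

Intracellular signaling dynamics — here the phosphorylation time course of
Erk downstream of T cell receptor stimulation — can be steered with
small-molecule reagents added as boluses: a phosphatase (MKP-1-like)
inhibitor that elevates and sustains phospho-Erk, and a Mek inhibitor that
suppresses it. Measurement assays (quantitative immunoblots) are far too
slow for feedback control, so the dosing regimen must be designed entirely
in advance: open-loop control. Any single ODE model of the pathway is a
rough approximation, and controllers built on one model inherit its
blind spots. This package implements a control strategy that blends a
*bank* of models inside a receding-horizon loop, weighting each model's
advice by how credible it is *in the region of input space where the
candidate dose lives*, as learned from preexisting dose-response data.

## The machinery

**Model bank (state-space form).** Each prediction model is
$\dot x = f(x,u,t,\theta)$, $y = g(\cdot)$, $z = h(\cdot)$ with $z$ the
normalized controlled output. Models are normalized so the peak of the
uncontrolled output is 1 (`calibrate_normalization()`), which puts
structurally different models on a common response scale. Boluses are
persistent: a dose adds to a standing input-concentration state that is
never washed out, entering the rate laws through saturating terms
$u/(u+K)$; dose times are integration breakpoints so boluses are resolved
exactly (`simulate_model()`, lsoda with rtol $10^{-7}$ / atol $10^{-9}$).

**Training data.** The screening protocol is fourteen experiments: a
control, five single doses of the phosphatase inhibitor (0.5–50 µM, added
at 15 min), five single doses of the kinase inhibitor (0.5–10 µM, at
6 min) and three combinations (at 6 min). The synthetic generator samples
the designated plant's output at 31 evenly spaced raw times per experiment
(434 points total, the data volume of the full study; `n_timepoints = 10`
gives the 140-point limited-data variant) and adds i.i.d. Gaussian noise
with standard deviation `noise_sd` × peak (default 0.05), emulating
roughly uniform error bars on the normalized immunoblot scale. Raw courses
are smoothed with a cubic smoothing spline in the `csaps` convention,
$p\sum_i (y_i - s(t_i))^2 + (1-p)\int s''^2$ with $p = 0.6$, and resampled
at 31 evenly spaced times. The $p$-convention matters: any other smoothing
parameterization would silently change what $p = 0.6$ means, so the
Green–Silverman natural-spline algebra is implemented directly.

**Weight maps.** Model credibility over the admissible input box
$\Omega = [0,50] \times [0,10]$ µM is scored by the small-sample-corrected
AIC,
$$\mathrm{AICc}_i = \sum_j n_j \ln(\mathrm{RSS}_{ij}/n_j) + 2k_i +
  \frac{2k_i(k_i+1)}{n-k_i-1},$$
converted to Akaike weights $w_i \propto e^{-\Delta_i/2}$ (computed in
log-space). Between training doses, both the smoothed data and each
model's predictions are interpolated with the *same* piecewise-linear
Delaunay barycentric operator over the scattered dose points (linear along
the shared resampled time grid), so a query compares like with like;
model predictions are first passed through the identical raw-sampling and
smoothing pipeline, so residuals measure model–data disagreement rather
than spline bias. Queries outside the convex hull of the training doses
clamp to the nearest hull point (and are logged as extrapolation). The RSS
at a query is the mean squared residual on the dense grid rescaled to the
raw measurement count, so that $n$ in the AICc is the number of actual
measurements; this reproduces the characteristic sharpening of the maps
with data volume (large-$n$ maps look nearly "digital", small-$n$ maps are
smooth, while the model *rankings* stay essentially unchanged —
`ranking_agreement()`).

**Per-interval objectives and surrogates.** For dosing interval
$[t_k, t_k + 5]$ the per-model tracking objective is
$J_i = \sum_m (\hat z_m - r_m)^2 + \bar u^\top R \bar u$ sampled at 1-min
resolution, returned as $\ln(J + 10^{-12})$ to compress the cost surface.
$\hat z$ is simulated from the *model's own current state* under the
candidate bolus (horizons $H_u = H_p = 1$ interval, which keeps the
controllers from being overly conservative). Each objective is replaced by
an error-controlled sparse-grid surrogate over $\Omega$ — nested,
boundary-including nodes with a hierarchical piecewise-multilinear basis,
refined until the largest new hierarchical surplus meets the absolute
(0.01) or relative (1% of range) tolerance or depth 6 — after which the
multiobjective stage needs no further ODE solves. Surrogates are optional:
`use_surrogate = FALSE` gives direct-evaluation callables with the same
contract and (to lattice resolution) the same selected inputs.

**Pareto front and input selection.** The per-interval multiobjective
problem is solved with the normalized normal constraint method: minimize
each objective individually (multistart bound-constrained SLSQP seeded
from a coarse lattice), normalize objectives so each anchor maps to 0 and
the worst anchor value to 1, distribute `n_pareto = 15` points on the
utopia hyperplane, and solve one normal-hyperplane-constrained scalar
subproblem per point; a Pareto filter removes dominated and duplicate
solutions. The committed input is chosen by ranking the front with the
weighted sum $\omega^\top J$ and iteratively recalibrating
$\omega \leftarrow \omega(u)$ at the currently selected input until
neither weights (`tol_w` $10^{-3}$) nor input (`tol_u` = 1% of the widest
input range) move, with a cap of 10 iterations; an exactly recurring input
is a limit cycle, resolved by one final ranking under the cycle-averaged
weights. At the first interval no candidate exists yet, so the initial
weights are computed from the entire training set; each interval then
seeds the next. The committed bolus advances every model's state and the
horizon slides on, producing the complete open-loop sequence $U^*$.

## Choices where the design was genuinely open

* **Windowed recalibration (default).** Weights may be recalibrated
  against the whole time course or only the training data inside the
  current prediction interval's time window; both are implemented and
  windowed is the default, since the point of adaptation is that different
  models are trustworthy in different *phases* of the response.
* **Recalibration coordinate.** Recalibration happens at the interval's
  candidate input vector. Recalibrating at the cumulative standing dose
  was tried and rejected: once the first reagent is on board, every later
  query lands in regions dominated by that reagent and the map can never
  switch advisors for the shutdown bolus.
* **Effort weight.** $Q$ is identity. $R$ defaults to $0.05 I$ acting on
  bound-normalized inputs $u/u_{\mathrm{hi}}$ (so the two reagents'
  µM scales are charged comparably). With $R = I$ on this scale a full
  phosphatase-inhibitor bolus costs 1.0 against tracking stakes of order
  0.3, and no controller would ever prescribe the tens-of-µM boluses the
  protocol is built around; $0.05$ keeps the effort term as a regularizer
  of otherwise flat cost regions.
* **Target family.** $r(t) = (1 - e^{-t/\tau_r})\,[p_{ss} +
  (1-p_{ss})/(1 + e^{(t-t_{off})/\tau_f})]$ with
  $\tau_r = \tau_f = 1$ min: fast activation to maximal response, a hold,
  and a smooth drive to the steady-state fraction $p_{ss}$ from
  $t_{off}$. The ten case-study pairs ship as `target_preset()`.
* **AICc aggregation.** The per-output form
  $\sum_j n_j\ln(\mathrm{RSS}_j/n_j)$ reduces to the standard
  least-squares AICc for a single output.
* **Sparse-grid error estimate.** The classical heuristic (largest
  hierarchical surplus on the newest level); "relative" tolerance is
  relative to the observed function range.
* **NNC resolution.** 15 utopia-plane points per interval; duplicate
  solutions collapse at $10^{-6}$ in normalized objective space.

## The miniature model bank

Reimplementing the published TCR pathway models (a 24-ODE kinetic model, a
37-ODE model with feedback, and a 40-state continuous-logic conversion) is
out of scope; the bank substitutes three miniature, structurally distinct
models of the same biology — a step stimulus driving a three-tier
phosphorylation relay whose terminal phosphoprotein is the output:

* **A** — pure mass-action with first-order receptor adaptation to a basal
  level: an early transient that relaxes to roughly 2/3 of peak. Its
  kinase-inhibitor pharmacology is accurate, but it badly *underestimates*
  the phosphatase inhibitor (half-effect 18 µM vs the plant's 4 µM, and
  half the attainable effect), so controllers built on A over-dose that
  reagent.
* **B** — mass-action with a slow negative loop (the output induces its
  own phosphatase, MKP-1-like) and a positive loop on the middle tier. Its
  baseline and phosphatase-inhibitor responses closely track the plant's,
  but it *overestimates* kinase-inhibitor potency (half-effect 0.02 µM vs
  0.6 µM), so its controllers systematically under-dose that reagent.
* **C** — normalized Hill-type (continuous-logic) dynamics on $[0,1]$
  states with a slow desensitizer, and the accurate pharmacology on both
  reagents. C is the default designated plant.

The rate constants are fixture constants: fixed, documented in the source,
and chosen (not fit) so the qualitative trends of the training protocol
hold for every member — moderate-to-high phosphatase-inhibitor doses
elevate or sustain late phosphorylation, the kinase inhibitor reverses the
phosphorylation rate within two minutes even at its lowest tested dose,
and the kinase inhibitor overpowers the phosphatase inhibitor in
combination. The complementary mispredictions are deliberate: they make
the multiple-model problem non-vacuous, in the same way the published
models were each partially data-consistent.

## What the generator emulates — and what it does not

The synthetic data reproduce the design, sampling density, normalization
and roughly-uniform additive noise of the screening study. They do not
emulate replicate-to-replicate blot variability, loading-control
normalization artifacts, off-target reagent effects, or biological
drift between experiment days. Passing benchmarks on this generator shows
that the *algorithmic chain* (weight maps → surrogates → NNC → adaptive
ranking → receding horizon) behaves as designed under realistic noise; it
does not certify performance on any particular laboratory system.

## Numerical choices and degenerate inputs

Integration uses lsoda with rtol $10^{-7}$/atol $10^{-9}$ and dose times
as breakpoints (trajectories before the first nonzero bolus are bitwise
identical to the uncontrolled run). Dose sets that are affinely degenerate
interpolate along their line (off-line queries error with a remediation
hint); duplicate doses are merged. A numerically perfect fit (RSS = 0)
maps to $-\infty$ AICc and takes all the weight. Weighted-rank ties break
lexicographically on the input vector, making selection order-invariant
and deterministic end to end; the benchmark's only randomness is the
training-noise seed.

## Problem sizes

The default study conditions are the full sweep: 3 plant rotations × 10
targets × 5 controller runs, five dosing intervals each, NNC with 15
utopia points on sparse-grid surrogates — about 150 open-loop designs, a
few minutes of compute on one core (model dynamics and the surrogate
evaluation kernel are compiled C). Unit tests use reduced Pareto
resolution and surrogate depth where the full sizes add nothing to the
property under test.

## Known limitations

* Open-loop by design: no measurement feedback, so late-interval errors
  from earlier mis-dosing cannot be corrected, only anticipated.
* Horizon-1 greediness: a bolus that helps this interval may cost later
  ones (persistent reagents!); the matched controller pays the same
  price, so comparisons remain fair.
* The weight map assumes a model good at predicting a dose region's
  *data* gives good *advice* there; deliberately adversarial model banks
  can violate this.
* Weight maps interpolate linearly between training doses; strongly
  nonlinear dose-response between ladder points is invisible to them.
* The bank is a miniature analogue and quantitative results are specific
  to it. On this bank the adaptive-weight controller beats the mean of the
  mismatched single-model controllers and tracks the per-scenario best
  single model closely, while the fixed-equal-weight controller — helped
  by the log-space ranking, under which averaging tends to adopt whichever
  model predicts near-perfect tracking — is a much stronger baseline than
  one might expect; the adaptive-vs-equal-weight comparison is a
  statistical tie here. Larger, more heterogeneous banks (where a single
  compromise weighting cannot be simultaneously adequate in all input
  regions) are the regime the adaptive weighting is designed for.
* Weighted-rank selection trusts the locally best-fitting model's advice
  entirely once weights saturate; when *no* bank member fits a region,
  the chosen model is only "least bad" and hedging between members can
  be competitive.
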