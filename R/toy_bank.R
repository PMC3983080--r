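## Miniature three-member prediction-model bank.
##
## All members describe the same biology at different levels of abstraction:
## a step stimulus at t = 0 (receptor ligation) drives a three-tier
## phosphorylation relay (Raf -> Mek -> Erk-like); the normalized controlled
## output z is the terminal phosphoprotein. Two persistent bolus inputs act
## on the terminal tier through saturating Hill terms:
##   input 1 (phosphatase inhibitor, range [0, 50] uM) suppresses terminal
##     dephosphorylation -> elevated / sustained z;
##   input 2 (kinase inhibitor, range [0, 10] uM) suppresses terminal
##     phosphorylation -> rapid loss of z even at low doses.
## The members are deliberately complementary: each pair agrees on one input
## channel's pharmacology and disagrees on the other, so that no single
## member is uniformly best at predicting another member acting as the
## plant. Rate constants below are the package's fixture contract: fixed,
## documented, not fit to data.

hill01 <- function(conc, K) conc / (conc + K)

## Input pharmacology "types" shared across members (saturating efficacy
## emax and half-effect constant K, concentration units of the input).
.u1_true   <- list(K = 4, emax = 0.6)    # sanguinarine-like, potent
.u1_weak   <- list(K = 18, emax = 0.3)   # underestimates phosphatase potency
.u2_true   <- list(K = 0.6, emax = 0.98)  # U0126-like, potent at moderate dose
.u2_weak   <- list(K = 2.5, emax = 0.95) # believes the inhibitor is feeble

## --- Member A: pure mass-action cascade with receptor adaptation ---------
## The active receptor pool relaxes first order from 1 to a basal level Rb
## (internalization), giving an early dip to a lower plateau; tiers
## conserve total = 1 between phospho and unphospho forms. u1-weak /
## u2-true pharmacology: A gets the kinase-inhibitor dose-response right
## but badly underestimates the phosphatase inhibitor, so its controllers
## over-dose that reagent.
.params_A <- c(r1 = 0.18, Rb = 0.45, a1 = 0.5, b1 = 2.0, a2 = 1.5,
               b2 = 1.5, a3 = 2.0, b3 = 2.0,
               K1 = .u1_weak$K, e1 = .u1_weak$emax,
               K2 = .u2_true$K, e2 = .u2_true$emax)

.rhs_A <- function(x, u, t, p) {
  a3eff <- p[["a3"]] * (1 - p[["e2"]] * hill01(u[2], p[["K2"]]))
  b3eff <- p[["b3"]] * (1 - p[["e1"]] * hill01(u[1], p[["K1"]]))
  dX1p <- p[["a1"]] * x[["R"]] * x[["X1"]] - p[["b1"]] * x[["X1p"]]
  dX2p <- p[["a2"]] * x[["X1p"]] * x[["X2"]] - p[["b2"]] * x[["X2p"]]
  dX3p <- a3eff * x[["X2p"]] * x[["X3"]] - b3eff * x[["X3p"]]
  c(R = -p[["r1"]] * (x[["R"]] - p[["Rb"]]),
    X1 = -dX1p, X1p = dX1p,
    X2 = -dX2p, X2p = dX2p,
    X3 = -dX3p, X3p = dX3p)
}

## --- Member B: mass-action cascade with feedback loops -------------------
## Constant stimulus; one slow negative loop (the terminal phosphoprotein
## induces its own phosphatase, the adaptive transient - MKP-1-like
## induction) and one positive loop (terminal phosphoprotein potentiates
## tier 2 activation). u1-strong pharmacology (the inhibitor acts on the
## whole phosphatase pool, induced included); overestimates
## kinase-inhibitor potency, so its controllers underdose that reagent.
.params_B <- c(a1 = 0.45, b1 = 0.15, a2 = 0.8, b2 = 0.3,
               fp = 0.8, a3 = 1.0, b3 = 0.3, kp = 0.3, dp = 0.08,
               gP = 0.6,
               K1 = .u1_true$K, e1 = .u1_true$emax,
               K2 = .u2_weak$K, e2 = .u2_weak$emax)

.rhs_B <- function(x, u, t, p) {
  a3eff <- p[["a3"]] * (1 - p[["e2"]] * hill01(u[2], p[["K2"]]))
  dinh <- 1 - p[["e1"]] * hill01(u[1], p[["K1"]])
  b3eff <- p[["b3"]] * (1 + p[["gP"]] * x[["P"]]) * dinh
  a2eff <- p[["a2"]] * (1 + p[["fp"]] * x[["X3p"]])   # positive feedback
  dX1p <- p[["a1"]] * x[["X1"]] - p[["b1"]] * x[["X1p"]]
  dX2p <- a2eff * x[["X1p"]] * x[["X2"]] - p[["b2"]] * x[["X2p"]]
  dX3p <- a3eff * x[["X2p"]] * x[["X3"]] - b3eff * x[["X3p"]]
  c(X1 = -dX1p, X1p = dX1p,
    X2 = -dX2p, X2p = dX2p,
    X3 = -dX3p, X3p = dX3p,
    P = p[["kp"]] * x[["X3p"]] - p[["dp"]] * x[["P"]])
}

## --- Member C: normalized Hill-type dynamics on [0,1] states -------------
## Odefy-style continuous logic: each state relaxes toward a normalized
## Hill activation of its upstream input; a slow desensitizer state v
## produces the transient. u1-strong / u2-strong pharmacology (the default
## designated plant).
.params_C <- c(tau1 = 1.4, tauv = 8, Kv = 0.31, nv = 4, tau2 = 1.1,
               K12 = 0.4, n12 = 3, kf = 1.0, K23 = 0.45, n23 = 3, kd = 0.5,
               K1 = .u1_true$K, e1 = .u1_true$emax,
               K2 = .u2_true$K, e2 = .u2_true$emax)

nhill <- function(x, K, n) {
  ## normalized Hill function: 0 at 0, 1 at 1
  (x^n / (x^n + K^n)) * (1 + K^n)
}

.rhs_C <- function(x, u, t, p) {
  finh <- 1 - p[["e2"]] * hill01(u[2], p[["K2"]])
  dinh <- 1 - p[["e1"]] * hill01(u[1], p[["K1"]])
  dx1 <- ((1 - x[["v"]]) - x[["x1"]]) / p[["tau1"]]
  dv  <- (nhill(x[["x1"]], p[["Kv"]], p[["nv"]]) - x[["v"]]) / p[["tauv"]]
  dx2 <- (nhill(x[["x1"]], p[["K12"]], p[["n12"]]) - x[["x2"]]) / p[["tau2"]]
  dx3 <- p[["kf"]] * nhill(x[["x2"]], p[["K23"]], p[["n23"]]) * finh *
    (1 - x[["x3"]]) - p[["kd"]] * dinh * x[["x3"]]
  c(x1 = dx1, v = dv, x2 = dx2, x3 = dx3)
}

#' Miniature three-member signaling-cascade model bank
#'
#' Returns three structurally distinct prediction models of a
#' stimulus-driven three-tier phosphorylation cascade with two bolus inputs
#' (a phosphatase inhibitor on \[0, 50\] and a kinase inhibitor on
#' \[0, 10\]), each calibrated so its uncontrolled controlled-output peak is
#' 1:
#' \describe{
#'   \item{A}{pure mass-action relay with first-order receptor decay;}
#'   \item{B}{mass-action relay with one negative and one positive feedback
#'     loop;}
#'   \item{C}{normalized Hill-type (continuous-logic) dynamics on
#'     \[0, 1\] states.}
#' }
#' Member C is flagged as the default designated plant. The rate constants
#' are fixed, documented fixture constants chosen so the qualitative
#' dose-response trends of the training protocol hold for every member:
#' high doses of input 1 elevate/sustain the late response, input 2 causes
#' an immediate drop in the phosphorylation rate even at low doses, and
#' input 2 overpowers input 1 in combination.
#'
#' @param seed unused (the bank is deterministic); kept so registries can
#'   treat all generators uniformly.
#' @param calibrate logical; calibrate each member's output normalization
#'   (default TRUE).
#' @return A list with elements `models` (named list of three
#'   [prediction_model()] objects `A`, `B`, `C`), `plant_id` (`"C"`) and
#'   `space` (the case-study [input_space()]).
#' @examples
#' bank <- make_toy_bank()
#' names(bank$models)
#' @export
make_toy_bank <- function(seed = 1L, calibrate = TRUE) {
  one_out <- function(expr) expr
  mA <- prediction_model(
    model_id = "A",
    x0 = c(R = 1, X1 = 1, X1p = 0, X2 = 1, X2p = 0, X3 = 1, X3p = 0),
    params = .params_A, rhs = .rhs_A,
    measured_map = function(x, u, t, p) x[["X3p"]],
    controlled_map = function(x, u, t, p) x[["X3p"]],
    n_u = 2, k = 8,   # r1, Rb, a1, b1, a2, b2, a3, b3
    csym = "awmpc_derivsA", cinit = "awmpc_initA")
  mB <- prediction_model(
    model_id = "B",
    x0 = c(X1 = 1, X1p = 0, X2 = 1, X2p = 0, X3 = 1, X3p = 0, P = 0),
    params = .params_B, rhs = .rhs_B,
    measured_map = function(x, u, t, p) x[["X3p"]],
    controlled_map = function(x, u, t, p) x[["X3p"]],
    n_u = 2, k = 10,  # a1, b1, a2, b2, fp, a3, b3, kp, dp, gP
    csym = "awmpc_derivsB", cinit = "awmpc_initB")
  mC <- prediction_model(
    model_id = "C",
    x0 = c(x1 = 0, v = 0, x2 = 0, x3 = 0),
    params = .params_C, rhs = .rhs_C,
    measured_map = function(x, u, t, p) x[["x3"]],
    controlled_map = function(x, u, t, p) x[["x3"]],
    n_u = 2, k = 9,   # tau1, tauv, Kv, tau2, K12, kf, K23, kd, (n)
    csym = "awmpc_derivsC", cinit = "awmpc_initC")
  models <- list(A = mA, B = mB, C = mC)
  if (calibrate) models <- lapply(models, calibrate_normalization)
  list(models = models, plant_id = "C", space = input_space())
}
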