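#' Objective specification for the tracking controller
#'
#' Weighting matrices and horizon settings of the finite-horizon tracking
#' objective. `Q` weighs squared output-tracking error, `R` weighs squared
#' control effort on bound-normalized inputs (`u / u_hi`, so that reagents
#' with different concentration scales are charged comparably). Both default
#' to identity. A control/prediction horizon of one dosing interval keeps
#' the controller from being overly conservative; the bolus convention
#' holds the dose for the remainder of the prediction horizon.
#'
#' @param Q output-error weight matrix (or scalar).
#' @param R effort weight matrix (or scalar), on normalized inputs
#'   (default 0.05: the effort term regularizes degenerate flat regions of
#'   the tracking objective without forbidding the large boluses the dosing
#'   protocol is designed around).
#' @param H_u,H_p control and prediction horizons in dosing intervals
#'   (`H_u <= H_p`; defaults 1).
#' @param log_eps positive offset in the log-space transform
#'   `ln(J + log_eps)` (default 1e-12), needed so a perfect-tracking
#'   zero-effort objective has a finite log.
#' @param dt_sample within-horizon sampling resolution of the error sum
#'   (min, default 1).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(Q = 1, R = 0.05, H_u = 1, H_p = 1, log_eps = 1e-12,
                           dt_sample = 1) {
  if (length(Q) == 1) Q <- matrix(Q, 1, 1)
  ## scalar R is kept as-is and expanded to diag(R, n_u) at evaluation time
  stopifnot(H_u >= 1, H_p >= H_u, log_eps > 0, dt_sample > 0)
  structure(list(Q = Q, R = R, H_u = H_u, H_p = H_p, log_eps = log_eps,
                 dt_sample = dt_sample),
            class = "objective_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Target output trajectory
#'
#' The family of desired normalized-output profiles: rapid activation to
#' maximal response, a hold, then a smooth drive toward the steady-state
#' fraction `p_ss` beginning around `t_off` minutes:
#' \deqn{r(t) = (1 - e^{-t/\tau_r})\left[p_{ss} +
#'   \frac{1 - p_{ss}}{1 + e^{(t - t_{off})/\tau_f}}\right]}
#' with rise and fall time constants \eqn{\tau_r = \tau_f = 1} min.
#'
#' @param t_off turn-off time (min), in `(0, 30]`.
#' @param p_ss desired steady-state fraction of maximal activation, in
#'   \[0, 1\].
#' @return An object of class `target_trajectory` with `t_off`, `p_ss` and
#'   `value_fn(t)`.
#' @examples
#' r <- target_trajectory(22, 0)
#' r$value_fn(c(5, 22, 30))
#' @export
target_trajectory <- function(t_off, p_ss) {
  if (t_off <= 0 || t_off > 30) stop("target_trajectory: t_off must be in (0, 30]")
  if (p_ss < 0 || p_ss > 1) stop("target_trajectory: p_ss must be in [0, 1]")
  tau_r <- 1
  tau_f <- 1
  value_fn <- function(t) {
    (1 - exp(-t / tau_r)) *
      (p_ss + (1 - p_ss) / (1 + exp((t - t_off) / tau_f)))
  }
  structure(list(t_off = t_off, p_ss = p_ss, value_fn = value_fn),
            class = "target_trajectory")
}

#' The ten case-study target pairs
#'
#' Named preset of `(t_off, p_ss)` pairs spanning early/mid/late turn-off
#' times and full, three-quarter and half deactivation, plus the
#' no-turn-off sustained-maximal case.
#'
#' @return A data frame with columns `t_off` and `p_ss`.
#' @export
target_preset <- function() {
  data.frame(
    t_off = c(8, 15, 22, 8, 15, 22, 8, 15, 22, 30),
    p_ss = c(0, 0, 0, 0.25, 0.25, 0.25, 0.5, 0.5, 0.5, 1))
}

#' Default dosing grid of the case studies
#'
#' Five possible bolus times starting 3 min post-stimulation, spaced 5 min
#' apart.
#'
#' @return Numeric vector `c(3, 8, 13, 18, 23)`.
#' @export
dosing_times <- function() seq(3, 23, by = 5)

#' Finite-horizon tracking objective for one model (log-space)
#'
#' Simulates the model from its current interval state under the candidate
#' bolus, samples the predicted normalized output over the prediction
#' horizon at `dt_sample` resolution, and returns
#' \deqn{\ln\left(\sum_m (\hat z_m - r_m)^\top Q (\hat z_m - r_m) +
#'   \sum_{m < H_u} \bar u^\top R \bar u + \epsilon\right)}
#' where \eqn{\bar u} is the dose normalized by the input upper bounds.
#'
#' @param model a [prediction_model()].
#' @param state current augmented model state at `t_k` (or NULL for the
#'   model's initial state).
#' @param u_k candidate dose vector (a single bolus, held over the horizon).
#' @param target a [target_trajectory()].
#' @param spec an [objective_spec()].
#' @param interval `c(t_k, t_end)` prediction interval (min).
#' @param space the [input_space()] used for effort normalization.
#' @return Log-space objective value (scalar).
#' @export
tracking_objective <- function(model, state = NULL, u_k, target, spec,
                               interval, space = input_space()) {
  t_k <- interval[1]
  t_end <- interval[2]
  stopifnot(t_end > t_k)
  t_s <- seq(t_k + spec$dt_sample, t_end, by = spec$dt_sample)
  sched <- if (all(u_k == 0)) {
    bolus_schedule(space = space)
  } else {
    bolus_schedule(t_k, u_k, space = space)
  }
  sim <- simulate_model(model, sched, t_grid = c(t_k, t_s), state0 = state,
                        t0 = t_k)
  keep <- sim$t_grid > t_k + 1e-9
  zhat <- sim$z[keep, , drop = FALSE]
  r <- target$value_fn(sim$t_grid[keep])
  err <- 0
  for (m in seq_along(r)) {
    e <- zhat[m, ] - r[m]
    err <- err + as.numeric(t(e) %*% spec$Q %*% e)
  }
  ubar <- u_k / pmax(space$upper, 1e-300)
  Rm <- spec$R
  if (!is.matrix(Rm) || nrow(Rm) != length(ubar)) {
    Rm <- diag(as.numeric(Rm)[1], length(ubar))
  }
  effort <- as.numeric(t(ubar) %*% Rm %*% ubar)
  log(err + effort + spec$log_eps)
}

#' Per-interval objective surrogates for a model bank
#'
#' Builds one sparse-grid surrogate of the log-space tracking objective
#' over the input space per model (from each model's own current state), so
#' that the multiobjective stage needs no further ODE evaluations. With
#' `use_surrogate = FALSE`, direct-evaluation callables with the identical
#' contract are returned instead.
#'
#' @param models list of [prediction_model()]s.
#' @param states list of current augmented states (same order), or NULL
#'   entries for initial states.
#' @param target a [target_trajectory()].
#' @param spec an [objective_spec()].
#' @param interval `c(t_k, t_end)`.
#' @param space the [input_space()].
#' @param tol_abs,tol_rel,max_depth sparse-grid controls.
#' @param use_surrogate logical (default TRUE).
#' @return A list (one element per model) of functions `f(u) -> scalar`;
#'   each carries the underlying surrogate (if any) as attribute
#'   `"surrogate"`.
#' @export
build_objective_surrogates <- function(models, states, target, spec, interval,
                                       space = input_space(),
                                       tol_abs = 0.01, tol_rel = 0.01,
                                       max_depth = 6, use_surrogate = TRUE) {
  stopifnot(length(models) == length(states))
  lapply(seq_along(models), function(i) {
    direct <- function(u) tracking_objective(models[[i]], states[[i]], u,
                                             target, spec, interval, space)
    if (!use_surrogate) return(direct)
    s <- build_surrogate(direct, space, tol_abs = tol_abs,
                         tol_rel = tol_rel, max_depth = max_depth)
    ## lean evaluation path: clamp and scale inline (the NNC inner loop
    ## calls this tens of thousands of times per interval)
    lo <- space$lower
    wid <- pmax(space$upper - space$lower, 1e-300)
    lv <- s$levels
    nd <- s$node_set
    su <- s$surpluses
    f <- function(u) {
      x <- (pmin(pmax(u, space$lower), space$upper) - lo) / wid
      sg_eval_unit(lv, nd, su, x)
    }
    attr(f, "surrogate") <- s
    f
  })
}
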