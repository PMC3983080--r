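#' Admissible control-input space
#'
#' The bounded box \eqn{\Omega} of feasible control-input vectors. Every
#' candidate bolus considered by the controller, and every training dose,
#' must lie inside these bounds. The case-study default is
#' \eqn{[0, 50] \mu M} for the phosphatase inhibitor (input 1, sanguinarine-
#' like) and \eqn{[0, 10] \mu M} for the kinase inhibitor (input 2,
#' U0126-like).
#'
#' @param lower numeric vector of lower bounds, one per input.
#' @param upper numeric vector of upper bounds, `upper >= lower`
#'   componentwise.
#' @return An object of class `input_space` with elements `lower`, `upper`
#'   and `n_u`.
#' @examples
#' input_space()           # the [0,50] x [0,10] case-study default
#' input_space(0, 1)       # a single dimensionless input
#' @export
input_space <- function(lower = c(0, 0), upper = c(50, 10)) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)))
  if (any(lower > upper)) {
    stop("input_space: 'lower' must be <= 'upper' componentwise")
  }
  structure(list(lower = lower, upper = upper, n_u = length(lower)),
            class = "input_space")
}

#' @export
print.input_space <- function(x, ...) {
  cat(sprintf("<input_space> Omega, %d input(s)\n", x$n_u))
  for (j in seq_len(x$n_u)) {
    cat(sprintf("  u%d in [%g, %g]\n", j, x$lower[j], x$upper[j]))
  }
  invisible(x)
}

space_contains <- function(space, u, tol = 1e-9) {
  all(u >= space$lower - tol & u <= space$upper + tol)
}

#' Bolus dosing schedule
#'
#' A sequence of discrete reagent additions. Each row of `doses` is one
#' input vector \eqn{u \in \Omega} administered at the matching entry of
#' `dose_times` (minutes after stimulation). Boluses are persistent: a dose
#' raises a standing reagent concentration that is not washed out, and a
#' later dose adds to it.
#'
#' @param dose_times strictly increasing numeric vector of times (min).
#' @param doses numeric matrix with one row per dose time (or a vector for a
#'   single dose time / single input recycled appropriately).
#' @param space an [input_space()]; every dose must lie within its bounds.
#' @return An object of class `bolus_schedule`.
#' @examples
#' bolus_schedule(c(3, 8), rbind(c(10, 0), c(0, 2)))
#' @export
bolus_schedule <- function(dose_times = numeric(0), doses = NULL,
                           space = input_space()) {
  dose_times <- as.numeric(dose_times)
  if (length(dose_times) == 0L) {
    doses <- matrix(numeric(0), nrow = 0, ncol = space$n_u)
  } else {
    if (is.null(doses)) stop("bolus_schedule: 'doses' required")
    if (!is.matrix(doses)) doses <- matrix(doses, nrow = length(dose_times),
                                           byrow = TRUE)
    storage.mode(doses) <- "double"
  }
  if (nrow(doses) != length(dose_times)) {
    stop("bolus_schedule: one dose vector per dose time required")
  }
  if (length(dose_times) > 1 && any(diff(dose_times) <= 0)) {
    stop("bolus_schedule: 'dose_times' must be strictly increasing")
  }
  for (i in seq_along(dose_times)) {
    if (!space_contains(space, doses[i, ])) {
      stop(sprintf("bolus_schedule: dose at t=%g outside input-space bounds",
                   dose_times[i]))
    }
  }
  structure(list(dose_times = dose_times, doses = doses, space = space),
            class = "bolus_schedule")
}

#' @export
print.bolus_schedule <- function(x, ...) {
  cat(sprintf("<bolus_schedule> %d bolus(es)\n", length(x$dose_times)))
  for (i in seq_along(x$dose_times)) {
    cat(sprintf("  t=%5.1f min : (%s)\n", x$dose_times[i],
                paste(signif(x$doses[i, ], 4), collapse = ", ")))
  }
  invisible(x)
}

#' Prediction model for the model bank
#'
#' Wraps one ordinary differential equation model of the controlled system in
#' the general state-space form used throughout the package: dynamics
#' \eqn{\dot x = f(x, u, t, \theta)}, measured outputs
#' \eqn{y = g(x, u, t, \theta)} and controlled outputs
#' \eqn{z = h(x, u, t, \theta)}. Control inputs act as persistent
#' bolus-set concentrations: the state vector is augmented with `n_u` input
#' concentration states which `f` may read (via the `u` argument) and which a
#' bolus increments instantaneously.
#'
#' @param model_id short label used in registries, exports and messages.
#' @param x0 initial state vector (named; concentration-like model units).
#' @param params named numeric vector of rate constants \eqn{\theta}.
#' @param rhs function `(x, u, t, params)` returning `dx/dt` for the core
#'   states (the input states are held constant between boluses by the
#'   integrator, not by `rhs`).
#' @param measured_map function `(x, u, t, params)` returning the measured
#'   output(s) `y` (unnormalized).
#' @param controlled_map function `(x, u, t, params)` returning the
#'   controlled output(s) `z` (unnormalized; normalization is applied via
#'   `output_scale`, see [calibrate_normalization()]).
#' @param n_u number of control inputs.
#' @param k number of uncertain parameters charged to this model in the AICc
#'   complexity penalty; defaults to `length(params)`.
#' @param csym,cinit optional names of compiled (C-level) derivative and
#'   parameter-initialization routines; when the symbols are available the
#'   integrator uses them instead of the R `rhs` (identical dynamics, much
#'   faster).
#' @param output_scale positive normalization factor(s) dividing the raw
#'   controlled output; 1 until calibrated.
#' @return An object of class `prediction_model`.
#' @seealso [simulate_model()], [calibrate_normalization()], [make_toy_bank()]
#' @export
prediction_model <- function(model_id, x0, params, rhs, measured_map,
                             controlled_map, n_u = 2,
                             k = length(params), output_scale = 1,
                             csym = NULL, cinit = NULL) {
  stopifnot(is.character(model_id), length(model_id) == 1,
            is.numeric(x0), is.function(rhs), is.function(measured_map),
            is.function(controlled_map), n_u >= 1, k >= 1,
            all(output_scale > 0))
  x0 <- stats::setNames(as.numeric(x0), names(x0))
  structure(list(model_id = model_id, x0 = x0,
                 state_names = names(x0), n_x = length(x0),
                 params = params, rhs = rhs, measured_map = measured_map,
                 controlled_map = controlled_map, n_u = as.integer(n_u),
                 k = as.integer(k), output_scale = output_scale,
                 csym = csym, cinit = cinit),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model> '%s': %d states, %d inputs, k = %d\n",
              x$model_id, x$n_x, x$n_u, x$k))
  cat(sprintf("  output_scale = %s%s\n",
              paste(signif(x$output_scale, 6), collapse = ", "),
              if (identical(x$output_scale, 1)) " (uncalibrated)" else ""))
  invisible(x)
}

## Full augmented initial state: core states then input concentration states.
augmented_x0 <- function(model) {
  x0 <- c(model$x0, rep(0, model$n_u))
  names(x0) <- c(model$state_names, paste0("u", seq_len(model$n_u)))
  x0
}

## locate the DLL exposing a registered symbol (package or dev build)
.find_dll <- function(sym) {
  info <- tryCatch(getNativeSymbolInfo(sym), error = function(e) NULL)
  if (is.null(info)) return(NULL)
  info$dll[["name"]]
}

## deSolve-facing RHS over the augmented state.
derivs_factory <- function(model) {
  n_x <- model$n_x
  n_u <- model$n_u
  function(t, state, parms) {
    x <- state[seq_len(n_x)]
    u <- state[n_x + seq_len(n_u)]
    dx <- model$rhs(x, u, t, parms)
    if (any(!is.finite(dx))) {
      stop(sprintf("non-finite derivative in model '%s' at t=%.4g",
                   model$model_id, t), call. = FALSE)
    }
    list(c(dx, rep(0, n_u)))
  }
}

#' Simulate a prediction model under a bolus schedule
#'
#' Integrates the model ODEs piecewise between dose times with a
#' stiff-capable solver (lsoda, `rtol = 1e-7`, `atol = 1e-9`). Each bolus is
#' applied exactly at its dose time by adding the dose vector to the standing
#' input-concentration states; dose times are integration breakpoints, so
#' boluses are resolved exactly and the trajectory before the first nonzero
#' dose is bitwise identical to the uncontrolled run on the same grid.
#'
#' @param model a [prediction_model()]; optionally continued from a custom
#'   state via `state0` / `t0`.
#' @param schedule a [bolus_schedule()].
#' @param t_grid sample times (min), default a 0.2-min grid on \[0, 30\].
#' @param state0,t0 optional augmented initial state and start time, used by
#'   the receding-horizon controller to advance a model from its current
#'   interval state; default is the model's own `x0` at `t0 = 0` (with zero
#'   standing input concentrations).
#' @return An object of class `simulation_result`: `t_grid`, `states` (matrix,
#'   one column per augmented state), `y` and `z` matrices (controlled output
#'   normalized by the model's `output_scale`).
#' @examples
#' bank <- make_toy_bank()
#' res <- simulate_model(bank$models[[1]], bolus_schedule())
#' max(res$z)   # 1 for a calibrated member
#' @export
simulate_model <- function(model, schedule = bolus_schedule(),
                           t_grid = seq(0, 30, by = 0.2),
                           state0 = NULL, t0 = 0) {
  stopifnot(inherits(model, "prediction_model"),
            inherits(schedule, "bolus_schedule"))
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0)) stop("simulate_model: t_grid must be increasing")
  if (t_grid[1] < t0 - 1e-12) {
    stop("simulate_model: t_grid starts before the initial time t0")
  }
  x <- if (is.null(state0)) augmented_x0(model) else state0
  stopifnot(length(x) == model$n_x + model$n_u)

  ## keep only boluses with a nonzero component at or after t0
  keep <- rowSums(abs(schedule$doses)) > 0 & schedule$dose_times >= t0
  dt <- schedule$dose_times[keep]
  dm <- schedule$doses[keep, , drop = FALSE]

  derivs <- if (is.null(model$csym)) derivs_factory(model) else NULL
  ## boluses exactly at t0 (continuation case) apply before integrating
  hit0 <- which(abs(dt - t0) <= 1e-12)
  for (i in hit0) x[model$n_x + seq_len(model$n_u)] <-
      x[model$n_x + seq_len(model$n_u)] + dm[i, ]

  breaks <- unique(c(t0, dt[dt > t0 + 1e-12 & dt < max(t_grid)], max(t_grid)))
  out_t <- numeric(0)
  out_x <- NULL
  if (abs(t_grid[1] - t0) <= 1e-9) {     # grid includes the start time
    out_t <- t0
    out_x <- matrix(x, nrow = 1)
  }
  t_cur <- t0
  dll <- if (!is.null(model$csym)) .find_dll(model$csym) else NULL
  for (b in breaks[-1]) {
    seg_t <- unique(c(t_cur,
                      t_grid[t_grid > t_cur + 1e-12 & t_grid <= b + 1e-12],
                      b))
    sol <- if (!is.null(dll)) {
      deSolve::lsoda(y = x, times = seg_t, func = model$csym,
                     parms = unname(model$params), dllname = dll,
                     initfunc = model$cinit, rtol = 1e-7, atol = 1e-9)
    } else {
      deSolve::lsoda(y = x, times = seg_t, func = derivs,
                     parms = model$params, rtol = 1e-7, atol = 1e-9)
    }
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol))) {
      stop(sprintf(
        "integration failure in model '%s' on interval [%.3g, %.3g]",
        model$model_id, t_cur, b))
    }
    x <- sol[nrow(sol), -1]
    ## keep strictly-later grid points (segment end b may not be on the grid)
    ongrid <- sol[, 1] > t_cur + 1e-12 &
      vapply(sol[, 1], function(tt) any(abs(tt - t_grid) <= 1e-9), logical(1))
    out_t <- c(out_t, sol[ongrid, 1])
    out_x <- rbind(out_x, sol[ongrid, -1, drop = FALSE])
    ## apply boluses scheduled exactly at this breakpoint
    hit <- which(abs(dt - b) <= 1e-12)
    for (i in hit) x[model$n_x + seq_len(model$n_u)] <-
        x[model$n_x + seq_len(model$n_u)] + dm[i, ]
    t_cur <- b
  }
  rownames(out_x) <- NULL
  colnames(out_x) <- names(augmented_x0(model))

  n_x <- model$n_x
  ymat <- t(vapply(seq_along(out_t), function(i) {
    as.numeric(model$measured_map(out_x[i, seq_len(n_x)],
                                  out_x[i, n_x + seq_len(model$n_u)],
                                  out_t[i], model$params))
  }, numeric(length(model$measured_map(model$x0, rep(0, model$n_u), 0,
                                       model$params)))))
  zmat <- t(vapply(seq_along(out_t), function(i) {
    as.numeric(model$controlled_map(out_x[i, seq_len(n_x)],
                                    out_x[i, n_x + seq_len(model$n_u)],
                                    out_t[i], model$params))
  }, numeric(length(model$output_scale))))
  if (nrow(ymat) != length(out_t)) ymat <- t(ymat)
  if (nrow(zmat) != length(out_t)) zmat <- t(zmat)
  zmat <- sweep(zmat, 2, model$output_scale, "/")
  structure(list(t_grid = out_t, states = out_x, y = ymat, z = zmat,
                 model_id = model$model_id),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> model '%s', %d time points on [%g, %g] min\n",
              x$model_id, length(x$t_grid), min(x$t_grid), max(x$t_grid)))
  cat(sprintf("  z range: [%.4g, %.4g]\n", min(x$z), max(x$z)))
  invisible(x)
}

#' Calibrate output normalization to a unit uncontrolled peak
#'
#' Sets the model's `output_scale` so that the peak of the uncontrolled
#' (zero-input) controlled-output trajectory equals 1. This puts structurally
#' different bank members on a common normalized response scale; the
#' operation is idempotent and invariant to any fixed rescaling of the raw
#' controlled-output map.
#'
#' @param model a [prediction_model()].
#' @param t_grid time grid over which the uncontrolled peak is measured.
#' @return The model with `output_scale` set.
#' @export
calibrate_normalization <- function(model, t_grid = seq(0, 30, by = 0.2)) {
  raw <- model
  raw$output_scale <- rep(1, length(model$output_scale))
  res <- simulate_model(raw, bolus_schedule(), t_grid = t_grid)
  peak <- apply(res$z, 2, max)
  if (any(peak <= 0)) {
    stop(sprintf("calibrate_normalization: model '%s' has nonpositive ",
                 model$model_id), "uncontrolled peak (degenerate model)")
  }
  model$output_scale <- peak
  model
}

#' Export a simulation as a tidy data frame
#'
#' Long-format trajectories (`model_id`, `time_min`, `variable`, `value`)
#' suitable for CSV export and plotting.
#'
#' @param result a `simulation_result` from [simulate_model()].
#' @param what which blocks to include: states, measured and/or controlled
#'   outputs.
#' @return A data frame.
#' @export
tidy_simulation <- function(result, what = c("z", "y", "states")) {
  what <- match.arg(what, several.ok = TRUE)
  blocks <- list()
  grab <- function(mat, prefix) {
    cn <- colnames(mat)
    if (is.null(cn)) cn <- paste0(prefix, seq_len(ncol(mat)))
    do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
      data.frame(model_id = result$model_id, time_min = result$t_grid,
                 variable = cn[j], value = mat[, j],
                 stringsAsFactors = FALSE)
    }))
  }
  if ("states" %in% what) blocks$states <- grab(result$states, "x")
  if ("y" %in% what) blocks$y <- grab(result$y, "y")
  if ("z" %in% what) blocks$z <- grab(result$z, "z")
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
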