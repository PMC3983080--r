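#' The 14-experiment dose-response training design
#'
#' Reproduces the screening design used to train the model weight maps:
#' one unperturbed control, a five-dose ladder of the phosphatase inhibitor
#' (0.5, 2, 5, 20, 50) administered at 15 min, a five-dose ladder of the
#' kinase inhibitor (0.5, 1, 2, 5, 10) administered at 6 min, and three dose
#' combinations (0.5, 1), (50, 1) and (50, 10) administered at 6 min.
#'
#' @param space a two-input [input_space()]; doses must fit inside it.
#' @return A data frame with columns `experiment_id`, `dose_1`, `dose_2`,
#'   `dose_time_min` (the control row has dose time `NA`).
#' @examples
#' nrow(generate_training_design())   # 14
#' @export
generate_training_design <- function(space = input_space()) {
  if (space$n_u != 2) {
    stop("generate_training_design: the screening design assumes 2 inputs")
  }
  u1 <- c(0.5, 2, 5, 20, 50)
  u2 <- c(0.5, 1, 2, 5, 10)
  combos <- rbind(c(0.5, 1), c(50, 1), c(50, 10))
  design <- data.frame(
    experiment_id = c("control",
                      paste0("u1_", u1),
                      paste0("u2_", u2),
                      paste0("combo_", combos[, 1], "_", combos[, 2])),
    dose_1 = c(0, u1, rep(0, 5), combos[, 1]),
    dose_2 = c(0, rep(0, 5), u2, combos[, 2]),
    dose_time_min = c(NA, rep(15, 5), rep(6, 5), rep(6, 3)),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(design))) {
    if (!space_contains(space, c(design$dose_1[i], design$dose_2[i]))) {
      stop("generate_training_design: design dose outside input space")
    }
  }
  design
}

#' Simulate noisy training time courses from a designated plant
#'
#' Runs the plant model through every experiment of a training design,
#' samples the normalized controlled output at `n_timepoints` raw times
#' evenly spread over \[0, 30\] min, and adds i.i.d. Gaussian observation
#' noise with standard deviation `noise_sd` times the plant's peak response
#' (error bars on normalized immunoblot data are roughly uniform on the
#' normalized scale). Each experiment is then smoothed and resampled with
#' [smooth_resample()].
#'
#' @param plant a calibrated [prediction_model()] acting as the data source.
#' @param design a design data frame from [generate_training_design()].
#' @param noise_sd noise fraction of peak (default 0.05).
#' @param n_timepoints raw sample times per experiment (default 31,
#'   giving a 434-point training set, the data volume of the full
#'   screening study; 10 gives the 140-point limited-data variant).
#' @param seed integer RNG seed; same seed, same dataset.
#' @param space the [input_space()] for schedule validation.
#' @param smooth_p,n_smooth smoothing weight and resample length forwarded
#'   to [smooth_resample()].
#' @return An object of class `training_dataset`: `experiments` (list of
#'   `training_experiment` records with `t_samples`, `y_raw`), `design`,
#'   `t_smooth`, `y_smooth` (matrix, experiments x resampled grid), and
#'   `n_total` (total raw measurement count across experiments/outputs).
#' @examples
#' bank <- make_toy_bank()
#' td <- simulate_training_data(bank$models$C, seed = 1)
#' td$n_total   # 14 experiments x 31 raw points
#' @export
simulate_training_data <- function(plant, design = generate_training_design(),
                                   noise_sd = 0.05, n_timepoints = 31,
                                   seed = 1L, space = input_space(),
                                   smooth_p = 0.6, n_smooth = 31) {
  stopifnot(noise_sd >= 0, n_timepoints >= 4)
  set.seed(as.integer(seed))
  t_raw <- seq(0, 30, length.out = n_timepoints)
  experiments <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    dose <- c(design$dose_1[i], design$dose_2[i])
    sched <- if (all(dose == 0) || is.na(design$dose_time_min[i])) {
      bolus_schedule(space = space)
    } else {
      bolus_schedule(design$dose_time_min[i], dose, space = space)
    }
    sim <- simulate_model(plant, sched, t_grid = t_raw)
    y_true <- sim$z[, 1]
    y_raw <- y_true + stats::rnorm(length(y_true), sd = noise_sd * max(1e-12, max(abs(y_true))))
    experiments[[i]] <- structure(
      list(experiment_id = design$experiment_id[i], dose = dose,
           dose_time = design$dose_time_min[i], t_samples = t_raw,
           y_raw = y_raw, y_true = y_true, n_replicates = 1L),
      class = "training_experiment")
  }
  t_smooth <- seq(min(t_raw), max(t_raw), length.out = n_smooth)
  y_smooth <- t(vapply(experiments, function(e) {
    smooth_resample(e, p = smooth_p, n_out = n_smooth)$y
  }, numeric(n_smooth)))
  rownames(y_smooth) <- design$experiment_id
  structure(list(experiments = experiments, design = design,
                 t_smooth = t_smooth, y_smooth = y_smooth,
                 n_total = length(t_raw) * nrow(design),
                 t_raw = t_raw, smooth_p = smooth_p,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 plant_id = plant$model_id),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat(sprintf(paste0("<training_dataset> %d experiments from plant '%s', ",
                     "%d raw points, noise_sd = %g\n"),
              length(x$experiments), x$plant_id, x$n_total, x$noise_sd))
  invisible(x)
}

#' Cubic smoothing spline in the csaps convention, resampled evenly
#'
#' Fits the natural cubic smoothing spline minimizing
#' \deqn{p \sum_i (y_i - s(t_i))^2 + (1 - p) \int s''(t)^2 dt}
#' (the MATLAB `csaps` parameterization: `p = 1` interpolates, `p = 0` is
#' the least-squares line) and evaluates it at `n_out` evenly spaced times
#' spanning the raw time range. Used to filter spurious oscillations from
#' noisy time courses while retaining the primary trends, and to densify
#' the time grid backing the weight-map interpolant.
#'
#' @param exp a `training_experiment` (or any list with `t_samples` and
#'   `y_raw`).
#' @param p smoothing weight in \[0, 1\] (default 0.6).
#' @param n_out number of evenly spaced output times (default 31).
#' @return A list with `t` (length `n_out`), `y` (smoothed values), and
#'   `fitted` (the spline at the raw times).
#' @export
smooth_resample <- function(exp, p = 0.6, n_out = 31) {
  t_raw <- exp$t_samples
  y_raw <- exp$y_raw
  if (length(t_raw) < 4) stop("smooth_resample: need at least 4 raw points")
  if (p < 0 || p > 1) stop("smooth_resample: p must lie in [0, 1]")
  sp <- csaps_fit(t_raw, y_raw, p)
  t_out <- seq(min(t_raw), max(t_raw), length.out = n_out)
  list(t = t_out, y = csaps_eval(sp, t_out), fitted = sp$f)
}

## Natural cubic smoothing spline, Green & Silverman band-matrix algebra.
## Minimizes p * ||y - f||^2 + (1 - p) * f' K f with K = Q R^-1 Q^T.
csaps_fit <- function(t, y, p) {
  n <- length(t)
  stopifnot(length(y) == n, n >= 4, all(diff(t) > 0))
  if (p == 0) {                       # least-squares straight line
    co <- stats::lm.fit(cbind(1, t), y)$coefficients
    return(list(t = t, f = co[1] + co[2] * t,
                gamma = rep(0, n), linear = TRUE, coef = co))
  }
  h <- diff(t)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    i <- j - 1                        # column index
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j, i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) {
      R[i, i + 1] <- h[j] / 6
      R[i + 1, i] <- h[j] / 6
    }
  }
  K <- Q %*% solve(R, t(Q))
  f <- solve(p * diag(n) + (1 - p) * K, p * y)
  gamma <- c(0, solve(R, crossprod(Q, f)), 0)  # natural: s'' = 0 at ends
  list(t = t, f = as.numeric(f), gamma = as.numeric(gamma), linear = FALSE)
}

csaps_eval <- function(sp, x) {
  if (isTRUE(sp$linear)) return(sp$coef[1] + sp$coef[2] * x)
  t <- sp$t
  f <- sp$f
  g <- sp$gamma
  idx <- pmin(pmax(findInterval(x, t), 1L), length(t) - 1L)
  h <- t[idx + 1] - t[idx]
  a <- t[idx + 1] - x
  b <- x - t[idx]
  ## value of the natural cubic with second derivatives g at the knots
  (a * f[idx] + b * f[idx + 1]) / h -
    a * b / 6 * ((1 + a / h) * g[idx] + (1 + b / h) * g[idx + 1])
}

#' Write / read training data in the tidy CSV schema
#'
#' Columns: `experiment_id, dose_1, dose_2, dose_time_min, time_min,
#' output_id, value, replicate`. Real experimental data in this schema can
#' be read interchangeably with synthetic data.
#'
#' @param dataset a `training_dataset`.
#' @param path CSV file path.
#' @return `write_training_csv` returns `path` invisibly;
#'   `read_training_csv` returns a `training_dataset` (smoothed on read).
#' @export
write_training_csv <- function(dataset, path) {
  rows <- do.call(rbind, lapply(dataset$experiments, function(e) {
    data.frame(experiment_id = e$experiment_id,
               dose_1 = e$dose[1], dose_2 = e$dose[2],
               dose_time_min = e$dose_time,
               time_min = e$t_samples, output_id = "z1",
               value = e$y_raw, replicate = 1L,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_csv
#' @param smooth_p,n_smooth smoothing settings applied on read.
#' @export
read_training_csv <- function(path, smooth_p = 0.6, n_smooth = 31) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "dose_1", "dose_2", "dose_time_min",
            "time_min", "output_id", "value")
  if (!all(need %in% names(rows))) {
    stop("read_training_csv: missing columns: ",
         paste(setdiff(need, names(rows)), collapse = ", "))
  }
  ids <- unique(rows$experiment_id)
  experiments <- lapply(ids, function(id) {
    ex <- rows[rows$experiment_id == id, ]
    ex <- ex[order(ex$time_min), ]
    structure(list(experiment_id = id,
                   dose = c(ex$dose_1[1], ex$dose_2[1]),
                   dose_time = ex$dose_time_min[1],
                   t_samples = ex$time_min, y_raw = ex$value,
                   n_replicates = max(1L, length(unique(ex$replicate)))),
              class = "training_experiment")
  })
  design <- do.call(rbind, lapply(experiments, function(e) {
    data.frame(experiment_id = e$experiment_id, dose_1 = e$dose[1],
               dose_2 = e$dose[2], dose_time_min = e$dose_time,
               stringsAsFactors = FALSE)
  }))
  t_all <- range(rows$time_min)
  t_smooth <- seq(t_all[1], t_all[2], length.out = n_smooth)
  ## evaluate every experiment's spline on the shared global grid
  y_smooth <- t(vapply(experiments, function(e) {
    csaps_eval(csaps_fit(e$t_samples, e$y_raw, smooth_p), t_smooth)
  }, numeric(n_smooth)))
  rownames(y_smooth) <- ids
  structure(list(experiments = experiments, design = design,
                 t_smooth = t_smooth, y_smooth = y_smooth,
                 n_total = nrow(rows),
                 t_raw = sort(unique(rows$time_min)), smooth_p = smooth_p,
                 noise_sd = NA_real_,
                 seed = NA_integer_, plant_id = NA_character_),
            class = "training_dataset")
}
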