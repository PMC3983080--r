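#' Corrected Akaike Information Criterion for least-squares fits
#'
#' Small-sample-corrected AIC assuming normally distributed errors with
#' constant variance, aggregated over measured outputs:
#' \deqn{AICc = \sum_j n_j \ln(RSS_j / n_j) + 2k + \frac{2k(k+1)}{n-k-1}}
#' with \eqn{n = \sum_j n_j} the total number of experimental data, `n_j`
#' the number of sampled points for output `j`, and `k` the number of
#' uncertain model parameters. Only differences in AICc between models are
#' meaningful.
#'
#' @param rss_per_output positive residual sums of squares, one per output.
#' @param n_per_output data counts per output.
#' @param k number of uncertain parameters.
#' @return AICc value (scalar).
#' @examples
#' aicc(2.5, 10, 3)   # 10*log(0.25) + 6 + 24/6
#' @export
aicc <- function(rss_per_output, n_per_output, k) {
  stopifnot(length(rss_per_output) == length(n_per_output), k >= 0)
  if (any(rss_per_output <= 0)) {
    stop("aicc: RSS must be positive (a perfect fit has no defined AICc)")
  }
  n <- sum(n_per_output)
  if (n <= k + 1) {
    stop(sprintf(
      "aicc: small-sample correction undefined for n = %g <= k + 1 = %g",
      n, k + 1))
  }
  sum(n_per_output * log(rss_per_output / n_per_output)) +
    2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' Relative likelihoods \eqn{w_i = \exp(-\Delta_i/2) / \sum_r
#' \exp(-\Delta_r/2)} with \eqn{\Delta_i = AICc_i - \min_r AICc_r}, computed
#' in log-space so that very large AICc differences do not underflow. An
#' infinite AICc receives weight 0; a `-Inf` AICc (a numerically perfect
#' fit) receives all the weight shared among such models.
#'
#' @param aicc_values numeric vector of AICc values (at least one finite or
#'   `-Inf`).
#' @return Weight vector summing to 1.
#' @examples
#' akaike_weights(c(10, 12))   # ~ (0.731, 0.269)
#' @export
akaike_weights <- function(aicc_values) {
  v <- stats::setNames(as.numeric(aicc_values), names(aicc_values))
  if (length(v) == 0 || all(is.na(v)) || all(v == Inf)) {
    stop("akaike_weights: need at least one finite (or -Inf) AICc value")
  }
  if (any(v == -Inf)) {
    w <- as.numeric(v == -Inf)
    names(w) <- names(v)
    return(w / sum(w))
  }
  d <- (v - min(v)) / 2
  lw <- -d - log(sum(exp(-d)))        # log-space normalization
  w <- exp(lw)
  w[v == Inf] <- 0
  w / sum(w)
}

#' Build Akaike-weight maps over the input space
#'
#' Trains the per-model AICc and Akaike-weight functions on a dose-response
#' training dataset. Each model is simulated once under every training
#' experiment's actual bolus schedule and its normalized prediction is
#' stored on the dataset's resampled time grid (the memoized prediction
#' bank). At a query dose `u`, both the smoothed data and every model's
#' predictions are blended with the same Delaunay barycentric weights, the
#' residual time course is converted to a residual sum of squares on the
#' raw-data scale (`RSS = n * mean squared residual`, with `n` the raw
#' measurement count, restricted proportionally under a time window), and
#' AICc / Akaike weights follow.
#'
#' @param models list of calibrated [prediction_model()] objects (the
#'   prediction bank; the plant itself is typically not a member).
#' @param dataset a `training_dataset`.
#' @param space the [input_space()] \eqn{\Omega}.
#' @return An object of class `weight_map` with functions `weight_fn(u,
#'   window = NULL)` and `aicc_fn(u, window = NULL)` (window = `c(t0, t1)`
#'   restricts the fitness evaluation to that time window), model ids,
#'   per-model `k`, and the supporting input/time spaces.
#' @examples
#' bank <- make_toy_bank()
#' td <- simulate_training_data(bank$models$C, seed = 1)
#' wm <- build_weight_map(bank$models[c("A", "B")], td)
#' wm$weight_fn(c(20, 0))
#' @export
build_weight_map <- function(models, dataset, space = input_space()) {
  stopifnot(length(models) >= 1, inherits(dataset, "training_dataset"))
  ids <- vapply(models, function(m) m$model_id, character(1))
  names(models) <- ids
  interp <- dataset_interpolant(dataset)
  t_grid <- dataset$t_smooth
  design <- dataset$design

  ## memoized per-model predictions under the actual training schedules,
  ## passed through the same raw-sampling + smoothing pipeline as the data
  ## so residuals measure model-data disagreement, not spline bias
  t_raw <- dataset$t_raw
  smooth_p <- if (is.null(dataset$smooth_p)) 0.6 else dataset$smooth_p
  pred <- lapply(models, function(m) {
    t(vapply(seq_len(nrow(design)), function(i) {
      dose <- c(design$dose_1[i], design$dose_2[i])
      sched <- if (all(dose == 0) || is.na(design$dose_time_min[i])) {
        bolus_schedule(space = space)
      } else {
        bolus_schedule(design$dose_time_min[i], dose, space = space)
      }
      z_raw <- simulate_model(m, sched, t_grid = t_raw)$z[, 1]
      csaps_eval(csaps_fit(t_raw, z_raw, smooth_p), t_grid)
    }, numeric(length(t_grid))))
  })
  k <- vapply(models, function(m) m$k, numeric(1))
  n_total <- dataset$n_total
  extrap_log <- new.env(parent = emptyenv())
  extrap_log$count <- 0L

  aicc_fn <- function(u, window = NULL) {
    if (!space_contains(space, u)) {
      stop("weight map query outside the admissible input space")
    }
    iw <- interp_weights(interp, u)
    if (iw$extrapolated) extrap_log$count <- extrap_log$count + 1L
    ydat <- as.numeric(crossprod(dataset$y_smooth[iw$idx, , drop = FALSE],
                                 iw$w))
    sel <- if (is.null(window)) {
      rep(TRUE, length(t_grid))
    } else {
      t_grid >= window[1] - 1e-9 & t_grid <= window[2] + 1e-9
    }
    if (!any(sel)) stop("weight map: empty time window")
    n_eff <- max(2, round(n_total * sum(sel) / length(t_grid)))
    vapply(ids, function(id) {
      ymod <- as.numeric(crossprod(pred[[id]][iw$idx, , drop = FALSE],
                                   iw$w))
      msr <- mean((ydat[sel] - ymod[sel])^2)
      rss <- n_eff * msr
      if (rss <= 0) return(-Inf)      # numerically perfect fit
      aicc(rss, n_eff, k[[id]])
    }, numeric(1))
  }
  weight_fn <- function(u, window = NULL) akaike_weights(aicc_fn(u, window))

  ## u-independent weights from the entire training set (first-interval
  ## initialization: no candidate input exists yet)
  global_weights <- function() {
    a <- vapply(ids, function(id) {
      msr <- mean((dataset$y_smooth - pred[[id]])^2)
      rss <- n_total * msr
      if (rss <= 0) return(-Inf)
      aicc(rss, n_total, k[[id]])
    }, numeric(1))
    akaike_weights(a)
  }

  structure(list(models = ids, k = k, aicc_fn = aicc_fn,
                 global_weights = global_weights,
                 weight_fn = weight_fn,
                 support = list(U = as.matrix(design[, c("dose_1", "dose_2")]),
                                T = t_grid),
                 n_total = n_total, space = space,
                 extrapolation_log = extrap_log),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map> models: %s | k: %s | n = %d\n",
              paste(x$models, collapse = ", "),
              paste(x$k, collapse = ", "), x$n_total))
  w0 <- x$weight_fn(colMeans(x$support$U))
  cat("  weights at the mean training dose:",
      paste(sprintf("%s=%.3f", x$models, w0), collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a weight map on a lattice and export to JSON
#'
#' Evaluates AICc values and Akaike weights on an `n1 x n2` lattice over
#' the input space and writes them (with metadata) to a JSON file, for
#' audit, plotting, or reuse.
#'
#' @param wmap a `weight_map`.
#' @param path output JSON path.
#' @param n1,n2 lattice resolution per input dimension.
#' @param window optional time window `c(t0, t1)`.
#' @return The lattice list, invisibly.
#' @export
export_weight_map <- function(wmap, path, n1 = 21, n2 = 21, window = NULL) {
  g1 <- seq(wmap$space$lower[1], wmap$space$upper[1], length.out = n1)
  g2 <- seq(wmap$space$lower[2], wmap$space$upper[2], length.out = n2)
  grid <- expand.grid(u1 = g1, u2 = g2)
  am <- t(apply(grid, 1, function(u) wmap$aicc_fn(as.numeric(u), window)))
  wm <- t(apply(am, 1, akaike_weights))
  colnames(am) <- colnames(wm) <- wmap$models
  out <- list(models = wmap$models, k = as.numeric(wmap$k),
              n = wmap$n_total, u1 = g1, u2 = g2,
              grid = grid, aicc = am, weights = wm,
              window = if (is.null(window)) NULL else window)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Ranking agreement between two weight maps
#'
#' Fraction of lattice points at which two weight maps rank the models in
#' the same order (argsort agreement). Used to probe robustness of the
#' model prioritization to the amount/quality of training data.
#'
#' @param wmap_a,wmap_b two `weight_map`s over the same models and space.
#' @param n1,n2 lattice resolution.
#' @param window optional time window.
#' @return Fraction in \[0, 1\].
#' @export
ranking_agreement <- function(wmap_a, wmap_b, n1 = 11, n2 = 11,
                              window = NULL) {
  stopifnot(identical(wmap_a$models, wmap_b$models))
  g1 <- seq(wmap_a$space$lower[1], wmap_a$space$upper[1], length.out = n1)
  g2 <- seq(wmap_a$space$lower[2], wmap_a$space$upper[2], length.out = n2)
  agree <- 0L
  for (a in g1) for (b in g2) {
    ra <- order(wmap_a$weight_fn(c(a, b), window), decreasing = TRUE)
    rb <- order(wmap_b$weight_fn(c(a, b), window), decreasing = TRUE)
    if (identical(ra, rb)) agree <- agree + 1L
  }
  agree / (n1 * n2)
}
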