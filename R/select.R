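#' Rank Pareto solutions by Akaike-weighted objective
#'
#' Selects the Pareto point minimizing the weighted sum
#' \eqn{\omega^\top J(U)} of the per-model log-space objective values.
#' Ties are broken deterministically by lexicographic order of the input
#' vector, so the winner does not depend on the order of the point list.
#'
#' @param pareto a `pareto_set` (or plain list of `list(U, J)` records).
#' @param weights model weight vector summing to 1, one entry per
#'   objective.
#' @return The winning record `list(U, J, ...)` with attribute `"score"`.
#' @export
rank_solutions <- function(pareto, weights) {
  pts <- if (inherits(pareto, "pareto_set")) pareto$points else pareto
  if (length(pts) == 0) stop("rank_solutions: empty Pareto set")
  weights <- as.numeric(weights)
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("rank_solutions: weights must sum to 1")
  }
  if (length(weights) != length(pts[[1]]$J)) {
    stop("rank_solutions: weight dimension does not match objectives")
  }
  scores <- vapply(pts, function(p) sum(weights * p$J), numeric(1))
  best <- which(scores <= min(scores) + 0)
  if (length(best) > 1) {
    ## lexicographic tie-break on the input vector
    Um <- do.call(rbind, lapply(pts[best], function(p) p$U))
    ord <- do.call(order, as.data.frame(Um))
    best <- best[ord[1]]
  }
  out <- pts[[best]]
  attr(out, "score") <- scores[best]
  out
}

#' Select the interval input with iterative weight adaptation
#'
#' Alternates Akaike-weighted ranking of the Pareto set and weight
#' recalibration at the currently selected input until neither the weights
#' nor the input change beyond their thresholds, the iteration cap is hit,
#' or a limit cycle is detected (a previously visited input recurs); a
#' cycle is resolved by a final ranking under the average of the weight
#' vectors in the cycle.
#'
#' @param pareto a `pareto_set`.
#' @param wmap a `weight_map` over the same models (or NULL to keep `w0`
#'   fixed, disabling adaptation).
#' @param w0 initial weight vector (at the first interval: the
#'   whole-training-set weights).
#' @param window optional time window forwarded to the weight map
#'   (windowed recalibration, the default controller mode).
#' @param u_standing standing input concentrations already on board from
#'   earlier boluses; weight recalibration is performed at the cumulative
#'   dose `u + u_standing` (clamped into the input space), the condition
#'   the system is actually in under the persistent-bolus convention.
#' @param tol_w weight-change threshold (default 1e-3).
#' @param tol_u input-change threshold (default: input-space width / 100).
#' @param max_iter iteration cap (default 10).
#' @return An object of class `selection_trace`: `iterations` (list of
#'   `list(u, weights, score)`), `terminated_by` (`"converged"`,
#'   `"limit_cycle"` or `"max_iter"`), `final_u`, `final_weights`.
#' @export
adapt_and_select <- function(pareto, wmap, w0, window = NULL,
                             u_standing = NULL,
                             tol_w = 1e-3, tol_u = NULL, max_iter = 10) {
  space <- pareto$space
  if (is.null(u_standing)) u_standing <- rep(0, space$n_u)
  if (is.null(tol_u)) tol_u <- max(space$upper - space$lower) / 100
  w <- as.numeric(w0) / sum(w0)
  iterations <- list()
  seen_u <- list()
  terminated <- "max_iter"
  final <- NULL
  for (it in seq_len(max_iter)) {
    pick <- rank_solutions(pareto, w)
    u <- pick$U
    iterations[[it]] <- list(u = u, weights = w,
                             score = attr(pick, "score"))
    ## limit-cycle check: exact recurrence of an earlier input (not the
    ## immediately preceding one, which is the convergence case)
    if (it >= 2) {
      prev_u <- iterations[[it - 1]]$u
      du <- max(abs(u - prev_u))
      dw <- max(abs(w - iterations[[it - 1]]$weights))
      if (du <= tol_u && dw <= tol_w) {
        terminated <- "converged"
        final <- list(u = u, w = w)
        break
      }
      cyc <- which(vapply(seen_u[seq_len(it - 2)], function(v)
        isTRUE(all(v == u)), logical(1)))
      if (length(cyc) > 0) {
        ## average the recalibrated weights at the cycle's inputs (the
        ## weight vectors of the iterations following the first visit)
        cyc_w <- do.call(rbind, lapply(iterations[(cyc[1] + 1):it],
                                       function(x) x$weights))
        w_avg <- colMeans(cyc_w)
        w_avg <- w_avg / sum(w_avg)
        pick <- rank_solutions(pareto, w_avg)
        iterations[[it + 1]] <- list(u = pick$U, weights = w_avg,
                                     score = attr(pick, "score"))
        terminated <- "limit_cycle"
        final <- list(u = pick$U, w = w_avg)
        break
      }
    }
    seen_u[[it]] <- u
    if (is.null(wmap)) {               # adaptation disabled (fixed weights)
      terminated <- "converged"
      final <- list(u = u, w = w)
      break
    }
    u_q <- pmin(pmax(u + u_standing, space$lower), space$upper)
    w_new <- as.numeric(wmap$weight_fn(u_q, window))
    if (max(abs(w_new - w)) <= tol_w) {
      terminated <- "converged"
      final <- list(u = u, w = w_new)
      break
    }
    w <- w_new
    final <- list(u = u, w = w)
  }
  structure(list(iterations = iterations, terminated_by = terminated,
                 final_u = final$u, final_weights = final$w),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d iteration(s), terminated by %s\n",
              length(x$iterations), x$terminated_by))
  cat("  final u: (", paste(signif(x$final_u, 5), collapse = ", "), ")\n")
  cat("  final weights:", paste(signif(x$final_weights, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a selection trace to JSON
#'
#' @param trace a `selection_trace`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
trace_to_json <- function(trace, path) {
  out <- list(iterations = lapply(trace$iterations, function(i)
    list(u = i$u, weights = i$weights, score = i$score)),
    terminated_by = trace$terminated_by,
    final_u = trace$final_u, final_weights = trace$final_weights)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
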