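## Normalized normal constraint (NNC) generation of per-interval Pareto
## sets. Each scalar subproblem minimizes the last normalized objective
## subject to the box bounds and the translated normal-hyperplane
## constraints; a Pareto filter removes dominated or duplicate solutions.

## bound-constrained local minimization with multistart
.multistart_min <- function(fn, space, n_starts = 5, hin = NULL) {
  ## n_starts = 5 for anchor solves; the hyperplane-constrained NNC
  ## subproblems use 3 (fronts identical on the reference problems, at a
  ## fraction of the cost)
  d <- space$n_u
  ## guard against the optimizer's finite-difference steps leaving the box
  fn_raw <- fn
  fn <- function(u) fn_raw(pmin(pmax(u, space$lower), space$upper))
  if (!is.null(hin)) {
    hin_raw <- hin
    hin <- function(u) hin_raw(pmin(pmax(u, space$lower), space$upper))
  }
  ## coarse lattice scan picks the most promising starts
  grids <- lapply(seq_len(d), function(j)
    seq(space$lower[j], space$upper[j], length.out = 5))
  lattice <- as.matrix(expand.grid(grids))
  fvals <- apply(lattice, 1, function(u) {
    v <- tryCatch(fn(u), error = function(e) Inf)
    if (!is.null(hin)) {
      g <- hin(u)
      if (any(g > 1e-8)) v <- Inf     # infeasible start (hin <= 0 feasible)
    }
    v
  })
  ord <- order(fvals)
  starts <- unique(lattice[ord[seq_len(min(n_starts, sum(is.finite(fvals))))], ,
                           drop = FALSE])
  if (nrow(starts) == 0) return(NULL)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch({
      if (is.null(hin)) {
        nloptr::slsqp(starts[s, ], fn, lower = space$lower,
                      upper = space$upper,
                      control = list(xtol_rel = 1e-5, maxeval = 30))
      } else {
        nloptr::slsqp(starts[s, ], fn, lower = space$lower,
                      upper = space$upper, hin = hin,
                      deprecatedBehavior = FALSE,
                      control = list(xtol_rel = 1e-5, maxeval = 30))
      }
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (!is.null(hin) && any(hin(res$par) > 1e-6)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

#' Anchor points and utopia/nadir normalization
#'
#' Minimizes each objective individually over the input space (multistart
#' bound-constrained local search seeded from a coarse lattice). The
#' normalization maps objective `i` so that its own anchor value becomes 0
#' and the worst value of objective `i` across all anchors (the nadir
#' estimate) becomes 1.
#'
#' @param objectives list of scalar functions on the space.
#' @param space an [input_space()].
#' @return A list with `minimizers` (matrix, one row per objective),
#'   `anchor_values` (matrix `f_i(u*_j)`), `utopia`, `nadir`, and
#'   `normalize(J)` mapping a raw objective vector to normalized space.
#' @export
anchor_points <- function(objectives, space) {
  n_m <- length(objectives)
  stopifnot(n_m >= 1)
  mins <- matrix(NA_real_, n_m, space$n_u)
  for (i in seq_len(n_m)) {
    best <- .multistart_min(objectives[[i]], space)
    if (is.null(best)) {
      stop(sprintf("anchor_points: optimizer failed for objective %d at all starts", i))
    }
    mins[i, ] <- best$par
  }
  ## anchor_values[i, j] = objective j evaluated at minimizer of objective i
  av <- matrix(NA_real_, n_m, n_m)
  for (i in seq_len(n_m)) for (j in seq_len(n_m)) {
    av[i, j] <- objectives[[j]](mins[i, ])
  }
  utopia <- diag(av)
  if (n_m == 1) utopia <- av[1, 1]
  nadir <- apply(av, 2, max)
  span <- pmax(nadir - utopia, 1e-12)   # degenerate-safe
  normalize <- function(J) (J - utopia) / span
  list(minimizers = mins, anchor_values = av, utopia = utopia,
       nadir = nadir, span = span, normalize = normalize)
}

#' Remove dominated and duplicate points
#'
#' Standard Pareto filter: a point is removed if another point is at least
#' as good in every objective and strictly better in one, or if it
#' duplicates an earlier point (within `tol` in objective space). Order of
#' the survivors is stable.
#'
#' @param points list of records each containing an objective vector `J`
#'   (or a numeric matrix with one row per point).
#' @param tol duplicate-collapse tolerance (default 1e-6).
#' @return The non-dominated subset, same representation as the input.
#' @export
pareto_filter <- function(points, tol = 1e-6) {
  was_matrix <- is.matrix(points)
  Jm <- if (was_matrix) points else
    do.call(rbind, lapply(points, function(p) p$J))
  n <- nrow(Jm)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (all(Jm[j, ] <= Jm[i, ]) && any(Jm[j, ] < Jm[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  idx <- which(keep)
  ## collapse duplicates (objective-space distance below tol)
  if (length(idx) > 1) {
    dup <- rep(FALSE, length(idx))
    for (a in seq_along(idx)) {
      if (dup[a]) next
      for (b in seq_along(idx)) {
        if (b <= a || dup[b]) next
        if (max(abs(Jm[idx[a], ] - Jm[idx[b], ])) < tol) dup[b] <- TRUE
      }
    }
    idx <- idx[!dup]
  }
  if (was_matrix) points[idx, , drop = FALSE] else points[idx]
}

## evenly distributed convex weights on the (n_m - 1)-simplex
.simplex_weights <- function(n_m, n_points) {
  if (n_m == 1) return(matrix(1, 1, 1))
  if (n_m == 2) {
    a <- seq(0, 1, length.out = n_points)
    return(cbind(a, 1 - a))
  }
  ## smallest lattice resolution giving at least n_points rows
  m <- n_m - 1
  res <- 1
  repeat {
    cnt <- choose(res + n_m - 1, n_m - 1)
    if (cnt >= n_points) break
    res <- res + 1
  }
  comps <- sg_compositions(res, n_m)
  comps / res
}

#' Generate the Pareto set by the normalized normal constraint method
#'
#' Computes the per-objective anchors, lays `n_points` evenly distributed
#' points on the utopia hyperplane, and for each solves the scalar
#' subproblem: minimize the last normalized objective subject to the input
#' bounds and the `n_M - 1` translated hyperplane constraints normal to the
#' utopia-plane vectors. Dominated or duplicate solutions are removed with
#' [pareto_filter()]. Infeasible subproblems are skipped (with a log
#' count); if every subproblem fails the call errors.
#'
#' @param objectives list of `n_M` scalar functions on the space (log-space
#'   tracking objectives in the controller).
#' @param space an [input_space()].
#' @param n_points number of utopia-plane points (default 15).
#' @return An object of class `pareto_set`: `points` (list of `list(U, J,
#'   J_norm)`), `anchors` (from [anchor_points()]), and `n_skipped`.
#' @examples
#' obj <- list(function(u) (u - 1)^2, function(u) (u + 1)^2)
#' ps <- generate_pareto_set(obj, input_space(-2, 2), n_points = 7)
#' range(vapply(ps$points, function(p) p$U, numeric(1)))   # ~ [-1, 1]
#' @export
generate_pareto_set <- function(objectives, space, n_points = 15) {
  n_m <- length(objectives)
  stopifnot(n_points >= n_m)
  anchors <- anchor_points(objectives, space)
  norm_obj <- lapply(seq_len(n_m), function(i) {
    function(u) (objectives[[i]](u) - anchors$utopia[i]) / anchors$span[i]
  })
  ## normalized anchor vectors mu_bar_i (rows)
  mu_bar <- t(apply(anchors$minimizers, 1, function(u)
    anchors$normalize(vapply(objectives, function(f) f(u), numeric(1)))))
  if (n_m == 1) mu_bar <- matrix(0, 1, 1)

  pts <- list()
  n_skipped <- 0L
  if (n_m == 1) {
    u <- anchors$minimizers[1, ]
    J <- vapply(objectives, function(f) f(u), numeric(1))
    pts[[1]] <- list(U = u, J = J, J_norm = anchors$normalize(J))
  } else {
    alphas <- .simplex_weights(n_m, n_points)
    ## utopia-plane direction vectors toward the last anchor
    Nk <- lapply(seq_len(n_m - 1), function(j) mu_bar[n_m, ] - mu_bar[j, ])
    ## memoize the normalized objective vector: the optimizer evaluates
    ## objective and constraints at the same points
    memo <- new.env(parent = emptyenv())
    memo$u <- NULL
    fbar <- function(u) {
      if (!is.null(memo$u) && identical(u, memo$u)) return(memo$fb)
      fb <- vapply(norm_obj, function(f) f(u), numeric(1))
      memo$u <- u
      memo$fb <- fb
      fb
    }
    for (r in seq_len(nrow(alphas))) {
      Xp <- as.numeric(t(mu_bar) %*% alphas[r, ])
      hin <- function(u) {
        fb <- fbar(u)
        ## feasible side: N_j . (fbar - Xp) <= 0
        vapply(Nk, function(Nj) sum(Nj * (fb - Xp)), numeric(1))
      }
      best <- .multistart_min(function(u) fbar(u)[n_m], space,
                              n_starts = 3, hin = hin)
      if (is.null(best)) {
        n_skipped <- n_skipped + 1L
        next
      }
      u <- pmin(pmax(best$par, space$lower), space$upper)
      J <- vapply(objectives, function(f) f(u), numeric(1))
      pts[[length(pts) + 1L]] <- list(U = u, J = J,
                                      J_norm = anchors$normalize(J))
    }
    ## the anchors themselves belong to the candidate set
    for (i in seq_len(n_m)) {
      u <- anchors$minimizers[i, ]
      J <- vapply(objectives, function(f) f(u), numeric(1))
      pts[[length(pts) + 1L]] <- list(U = u, J = J,
                                      J_norm = anchors$normalize(J))
    }
  }
  if (length(pts) == 0) {
    stop("generate_pareto_set: every NNC subproblem was infeasible")
  }
  pts <- pareto_filter(pts)
  structure(list(points = pts, anchors = anchors, n_skipped = n_skipped,
                 space = space),
            class = "pareto_set")
}

#' @export
print.pareto_set <- function(x, ...) {
  cat(sprintf("<pareto_set> %d non-dominated point(s), %d subproblem(s) skipped\n",
              length(x$points), x$n_skipped))
  invisible(x)
}

#' Dump a Pareto set to JSON
#'
#' @param ps a `pareto_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
pareto_to_json <- function(ps, path) {
  out <- list(
    points = lapply(ps$points, function(p)
      list(U = p$U, J = p$J, J_norm = p$J_norm)),
    anchors = list(minimizers = ps$anchors$minimizers,
                   utopia = ps$anchors$utopia, nadir = ps$anchors$nadir),
    n_skipped = ps$n_skipped)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
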