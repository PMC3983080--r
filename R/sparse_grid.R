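## Error-controlled sparse-grid interpolation surrogates on the input box.
## Nested, boundary-including (Clenshaw-Curtis-type) 1-D node family with a
## piecewise-multilinear hierarchical basis:
##   level 0: {1/2};  level 1: {0, 1};  level l >= 2: odd multiples of 2^-l.
## A surrogate at depth d combines all tensor levels with total level
## <= d - 1; refinement stops early when the largest hierarchical surplus
## on the newest level meets the absolute or relative tolerance.

sg_nodes_1d <- function(l) {
  if (l == 0) return(0.5)
  if (l == 1) return(c(0, 1))
  (2 * seq_len(2^(l - 1)) - 1) / 2^l
}

## 1-D hierarchical hat value at query x for a node (level l, position xn)
sg_phi_1d <- function(l, xn, x) {
  out <- numeric(length(xn))
  z0 <- l == 0
  z1 <- l == 1
  zh <- l >= 2
  out[z0] <- 1
  out[z1] <- ifelse(xn[z1] == 0, pmax(0, 1 - 2 * x), pmax(0, 2 * x - 1))
  if (any(zh)) out[zh] <- pmax(0, 1 - 2^l[zh] * abs(x - xn[zh]))
  out
}

## all compositions of total L into d nonnegative parts
sg_compositions <- function(L, d) {
  if (d == 1) return(matrix(L, 1, 1))
  out <- NULL
  for (first in 0:L) {
    rest <- sg_compositions(L - first, d - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

sg_eval_unit <- function(levels, coords, surplus, x) {
  if (length(surplus) == 0) return(0)
  if (.sg_have_c()) {
    return(.Call("awmpc_sg_eval", levels, coords, surplus,
                 as.numeric(x)))
  }
  val <- rep(1, nrow(coords))
  for (j in seq_len(ncol(coords))) {
    val <- val * sg_phi_1d(levels[, j], coords[, j], x[j])
  }
  sum(surplus * val)
}

.sg_have_c <- local({
  have <- NULL
  function() {
    if (is.null(have)) have <<- is.loaded("awmpc_sg_eval")
    have
  }
})

#' Build an error-controlled sparse-grid surrogate
#'
#' Interpolates a scalar function over the input box with a hierarchical
#' piecewise-multilinear sparse grid on nested boundary-including nodes.
#' Levels are added until the estimated interpolation error (the largest
#' hierarchical surplus on the newest level) meets the absolute tolerance
#' or the relative tolerance times the observed function range, or until
#' `max_depth` is reached; the stopping criterion is recorded.
#'
#' @param fn scalar function of an input vector on the space.
#' @param space an [input_space()].
#' @param tol_abs absolute error tolerance (default 0.01).
#' @param tol_rel relative error tolerance as a fraction of the observed
#'   function range (default 0.01, i.e. 1 percent).
#' @param max_depth maximum interpolation depth (default 6).
#' @return An object of class `sparse_surrogate` with node set, hierarchical
#'   surpluses, reported error estimates (`est_abs_err`, `est_rel_err`),
#'   `depth` used and `stopped_by` (`"tol_abs"`, `"tol_rel"` or
#'   `"max_depth"`).
#' @examples
#' s <- build_surrogate(function(u) u[1] + 2 * u[2], input_space(c(0, 0), c(1, 1)))
#' evaluate_surrogate(s, c(0.3, 0.7))
#' @export
build_surrogate <- function(fn, space, tol_abs = 0.01, tol_rel = 0.01,
                            max_depth = 6) {
  d <- space$n_u
  lo <- space$lower
  wid <- space$upper - space$lower
  fn_unit <- function(x) {
    v <- fn(lo + x * wid)
    if (!is.finite(v)) {
      stop(sprintf("build_surrogate: non-finite function value at (%s)",
                   paste(signif(lo + x * wid, 6), collapse = ", ")))
    }
    v
  }
  levels <- NULL
  coords <- NULL
  surplus <- numeric(0)
  fvals <- numeric(0)
  est_abs <- Inf
  stopped <- "max_depth"
  depth_used <- 0
  for (L in 0:(max_depth - 1)) {
    comps <- sg_compositions(L, d)
    new_lv <- NULL
    new_xy <- NULL
    for (r in seq_len(nrow(comps))) {
      lv <- comps[r, ]
      grids <- lapply(lv, sg_nodes_1d)
      pts <- as.matrix(expand.grid(grids))
      new_lv <- rbind(new_lv, matrix(lv, nrow(pts), d, byrow = TRUE))
      new_xy <- rbind(new_xy, unname(pts))
    }
    new_s <- numeric(nrow(new_xy))
    new_f <- numeric(nrow(new_xy))
    for (i in seq_len(nrow(new_xy))) {
      fv <- fn_unit(new_xy[i, ])
      new_f[i] <- fv
      new_s[i] <- fv - sg_eval_unit(levels, coords, surplus, new_xy[i, ])
    }
    storage.mode(new_lv) <- "double"
    storage.mode(new_xy) <- "double"
    est_abs <- max(abs(new_s))
    if (L >= 1 && est_abs == 0) {
      ## the new level contributes nothing; drop it and stop
      stopped <- "tol_abs"
      break
    }
    levels <- rbind(levels, new_lv)
    coords <- rbind(coords, new_xy)
    surplus <- c(surplus, new_s)
    fvals <- c(fvals, new_f)
    depth_used <- L + 1
    rng <- diff(range(fvals))
    if (L >= 1) {
      if (est_abs <= tol_abs) {
        stopped <- "tol_abs"
        break
      }
      if (est_abs <= tol_rel * rng) {
        stopped <- "tol_rel"
        break
      }
    }
  }
  rng <- diff(range(fvals))
  structure(list(dimension = d, bounds = space, levels = levels,
                 node_set = coords, surpluses = surplus, fvals = fvals,
                 est_abs_err = est_abs,
                 est_rel_err = if (rng > 0) est_abs / rng else 0,
                 depth = depth_used, max_depth = max_depth,
                 stopped_by = stopped),
            class = "sparse_surrogate")
}

#' @export
print.sparse_surrogate <- function(x, ...) {
  cat(sprintf(paste0("<sparse_surrogate> %d-D, depth %d (%d nodes), ",
                     "est abs err %.3g (stopped by %s)\n"),
              x$dimension, x$depth, length(x$surpluses), x$est_abs_err,
              x$stopped_by))
  invisible(x)
}

#' Evaluate a sparse-grid surrogate
#'
#' Hierarchical-basis evaluation at a point of the input space; continuous
#' in `u`, exact at every support node, deterministic. No extrapolation:
#' queries outside the bounds are an error.
#'
#' @param s a `sparse_surrogate`.
#' @param u input vector within the surrogate's bounds.
#' @return Scalar interpolated value.
#' @export
evaluate_surrogate <- function(s, u) {
  u <- as.numeric(u)
  if (!space_contains(s$bounds, u)) {
    stop("evaluate_surrogate: query outside the input space (no extrapolation)")
  }
  x <- (u - s$bounds$lower) / pmax(s$bounds$upper - s$bounds$lower, 1e-300)
  sg_eval_unit(s$levels, s$node_set, s$surpluses, x)
}

#' Time-resolved surrogate evaluation
#'
#' Evaluates a family of per-timepoint surrogates and interpolates linearly
#' between the grids placed at the anchor times, giving a trajectory that
#' is continuous in both `u` and `t`.
#'
#' @param surrogates list of `sparse_surrogate`s, one per anchor time.
#' @param times anchor times (same length, increasing).
#' @param u input vector.
#' @param t query time(s) within `range(times)`.
#' @return Numeric vector of interpolated values at `t`.
#' @export
evaluate_surrogate_trajectory <- function(surrogates, times, u, t) {
  stopifnot(length(surrogates) == length(times), !is.unsorted(times))
  vals <- vapply(surrogates, evaluate_surrogate, numeric(1), u = u)
  stats::approx(times, vals, xout = t, rule = 2)$y
}

#' Count the nodes of a full sparse grid at a given depth
#'
#' @param d dimension.
#' @param depth interpolation depth (levels 0 to `depth - 1`).
#' @return Integer node count.
#' @export
sparse_grid_size <- function(d, depth) {
  m <- function(l) if (l == 0) 1 else if (l == 1) 2 else 2^(l - 1)
  total <- 0
  for (L in 0:(depth - 1)) {
    comps <- sg_compositions(L, d)
    total <- total + sum(apply(comps, 1, function(lv)
      prod(vapply(lv, m, numeric(1)))))
  }
  as.integer(total)
}

#' Serialize / restore a sparse surrogate (JSON)
#'
#' @param s a `sparse_surrogate`.
#' @param path JSON file path.
#' @return `surrogate_to_json` returns `path` invisibly;
#'   `surrogate_from_json` returns the restored surrogate.
#' @export
surrogate_to_json <- function(s, path) {
  out <- list(dimension = s$dimension,
              lower = s$bounds$lower, upper = s$bounds$upper,
              levels = s$levels, nodes = s$node_set,
              surpluses = s$surpluses, fvals = s$fvals,
              est_abs_err = s$est_abs_err, est_rel_err = s$est_rel_err,
              depth = s$depth, max_depth = s$max_depth,
              stopped_by = s$stopped_by)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname surrogate_to_json
#' @export
surrogate_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- as.matrix(o$levels)
  nd <- as.matrix(o$nodes)
  storage.mode(lv) <- "double"
  storage.mode(nd) <- "double"
  structure(list(dimension = o$dimension,
                 bounds = input_space(o$lower, o$upper),
                 levels = lv, node_set = nd,
                 surpluses = o$surpluses, fvals = o$fvals,
                 est_abs_err = o$est_abs_err, est_rel_err = o$est_rel_err,
                 depth = o$depth, max_depth = o$max_depth,
                 stopped_by = o$stopped_by),
            class = "sparse_surrogate")
}
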