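## Piecewise-linear scattered-data interpolation over the dose space by
## Delaunay triangulation, with nearest-hull-point clamping outside the
## convex hull of the training doses. The triangulation is built once per
## dataset; data and per-model predictions are then blended with the same
## barycentric weights, so interpolated data and interpolated predictions
## stay exactly comparable at any query.

#' Piecewise-linear interpolant over scattered dose points
#'
#' Builds a Delaunay triangulation of the (deduplicated) dose points and
#' returns an object whose barycentric weights can be queried at any input
#' vector. Queries outside the convex hull are clamped to the nearest point
#' on the hull boundary (and flagged as extrapolated). Dose sets that are
#' affinely degenerate (all points on a line) fall back to 1-D linear
#' interpolation along that line; queries off the line are rejected with a
#' remediation hint.
#'
#' @param points numeric matrix (m x 2) of dose vectors.
#' @return An object of class `dose_interpolant`.
#' @keywords internal
dose_interpolant <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  ## collapse exact duplicates, remembering the merge map
  key <- paste(points[, 1], points[, 2], sep = "|")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  pts <- points[uniq, , drop = FALSE]
  m <- nrow(pts)
  sc <- pmax(apply(pts, 2, function(v) diff(range(v))), 1e-12)

  obj <- list(points = pts, map = map, m_all = nrow(points), scale = sc)
  if (m == 1) {
    obj$kind <- "point"
  } else {
    ctr <- sweep(pts, 2, colMeans(pts))
    dec <- svd(sweep(ctr, 2, sc, "/"))
    if (m == 2 || dec$d[2] < 1e-9 * dec$d[1]) {
      ## degenerate: all doses on a line; param by arclength projection
      dirv <- dec$v[, 1]
      s <- as.numeric(sweep(ctr, 2, sc, "/") %*% dirv)
      obj$kind <- "line"
      obj$dir <- dirv
      obj$center <- colMeans(pts)
      obj$s <- s
    } else {
      dd <- deldir::deldir(pts[, 1] / sc[1], pts[, 2] / sc[2],
                           suppressMsge = TRUE)
      tl <- deldir::triang.list(dd)
      tri <- t(vapply(tl, function(d) as.integer(d$ptNum), integer(3)))
      hull <- grDevices::chull(pts[, 1] / sc[1], pts[, 2] / sc[2])
      obj$kind <- "triangulated"
      obj$tri <- tri
      obj$hull <- hull
    }
  }
  class(obj) <- "dose_interpolant"
  obj
}

## Barycentric coordinates of p in triangle (a, b, c); NULL if degenerate.
.bary <- function(p, a, b, c) {
  M <- cbind(b - a, c - a)
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(dt) < 1e-14) return(NULL)
  lam <- solve(M, p - a)
  c(1 - sum(lam), lam)
}

## Nearest point on the hull boundary to query q (scaled coordinates).
.nearest_on_hull <- function(q, pts, hull) {
  best <- NULL
  bestd <- Inf
  nh <- length(hull)
  for (i in seq_len(nh)) {
    a <- pts[hull[i], ]
    b <- pts[hull[i %% nh + 1], ]
    ab <- b - a
    tt <- sum((q - a) * ab) / max(sum(ab * ab), 1e-300)
    tt <- min(max(tt, 0), 1)
    pr <- a + tt * ab
    d <- sum((q - pr)^2)
    if (d < bestd) {
      bestd <- d
      best <- pr
    }
  }
  best
}

#' Barycentric weights of an interpolation query
#'
#' @param interp a `dose_interpolant`.
#' @param u query dose vector.
#' @return list with `idx` (indices into the original point set), `w`
#'   (convex weights summing to 1) and `extrapolated` (TRUE if the query was
#'   clamped to the hull or line segment).
#' @keywords internal
interp_weights <- function(interp, u) {
  u <- as.numeric(u)
  pts <- interp$points
  sc <- interp$scale
  expand <- function(idx, w, extra) {
    ## spread weights back over duplicated original rows
    full_w <- numeric(interp$m_all)
    for (j in seq_along(idx)) {
      rows <- which(interp$map == idx[j])
      full_w[rows] <- full_w[rows] + w[j] / length(rows)
    }
    nz <- which(full_w != 0)
    list(idx = nz, w = full_w[nz], extrapolated = extra)
  }
  if (interp$kind == "point") {
    return(expand(1L, 1, !isTRUE(all.equal(u, pts[1, ], tolerance = 1e-9))))
  }
  if (interp$kind == "line") {
    rel <- (u - interp$center) / sc
    s_q <- sum(rel * interp$dir)
    perp <- sqrt(max(0, sum(rel^2) - s_q^2))
    if (perp > 1e-6) {
      stop("interpolation query lies off the line spanned by the training ",
           "doses (degenerate triangulation); add experiments varying the ",
           "missing input dimension")
    }
    s <- interp$s
    o <- order(s)
    s_q <- min(max(s_q, min(s)), max(s))       # clamp to the segment
    i <- pmin(pmax(findInterval(s_q, s[o]), 1L), length(s) - 1L)
    s1 <- s[o][i]
    s2 <- s[o][i + 1]
    lam <- if (s2 > s1) (s_q - s1) / (s2 - s1) else 0
    return(expand(c(o[i], o[i + 1]), c(1 - lam, lam),
                  s_q != sum(((u - interp$center) / sc) * interp$dir)))
  }
  q <- u / sc
  spts <- sweep(pts, 2, sc, "/")
  for (r in seq_len(nrow(interp$tri))) {
    v <- interp$tri[r, ]
    lam <- .bary(q, spts[v[1], ], spts[v[2], ], spts[v[3], ])
    if (!is.null(lam) && all(lam >= -1e-9)) {
      lam <- pmax(lam, 0)
      lam <- lam / sum(lam)
      return(expand(v, lam, FALSE))
    }
  }
  ## outside the hull: clamp to the nearest hull-boundary point
  pr <- .nearest_on_hull(q, spts, interp$hull)
  for (r in seq_len(nrow(interp$tri))) {
    v <- interp$tri[r, ]
    lam <- .bary(pr, spts[v[1], ], spts[v[2], ], spts[v[3], ])
    if (!is.null(lam) && all(lam >= -1e-6)) {
      lam <- pmax(lam, 0)
      lam <- lam / sum(lam)
      return(expand(v, lam, TRUE))
    }
  }
  stop("interpolation failed: query could not be located in the ",
       "triangulation even after hull clamping")
}

#' Interpolate training data at an arbitrary dose and time
#'
#' Piecewise-linear interpolation of the smoothed training time courses over
#' the (dose x time) space: Delaunay-barycentric over the scattered training
#' doses, linear along the shared resampled time grid. Outside the convex
#' hull of the training doses the value at the nearest hull point is
#' returned.
#'
#' @param dataset a `training_dataset`.
#' @param u dose vector.
#' @param t time (min), or a vector of times; defaults to the dataset's full
#'   smoothed grid.
#' @return Named list with `value` (interpolated value(s)) and
#'   `extrapolated`.
#' @examples
#' bank <- make_toy_bank()
#' td <- simulate_training_data(bank$models$C, seed = 1)
#' interpolate_training_data(td, c(5, 0), t = 15)$value
#' @export
interpolate_training_data <- function(dataset, u, t = NULL) {
  interp <- dataset_interpolant(dataset)
  iw <- interp_weights(interp, u)
  course <- as.numeric(crossprod(dataset$y_smooth[iw$idx, , drop = FALSE],
                                 iw$w))
  if (is.null(t)) {
    return(list(value = course, t = dataset$t_smooth,
                extrapolated = iw$extrapolated))
  }
  val <- stats::approx(dataset$t_smooth, course, xout = t, rule = 2)$y
  list(value = val, t = t, extrapolated = iw$extrapolated)
}

## cache the triangulation on the dataset object (environment-free memo)
dataset_interpolant <- function(dataset) {
  if (!is.null(attr(dataset, "interpolant"))) {
    return(attr(dataset, "interpolant"))
  }
  dose_interpolant(as.matrix(dataset$design[, c("dose_1", "dose_2")]))
}
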