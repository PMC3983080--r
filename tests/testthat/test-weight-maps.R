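test_that("AICc matches hand arithmetic and aggregation rules", {
  ## single output, n = 10, RSS = 2.5, k = 3:
  ## 10 ln(0.25) + 2*3 + 2*3*4 / (10 - 3 - 1) = -3.862944
  expect_equal(aicc(2.5, 10, 3), 10 * log(0.25) + 6 + 4,
               tolerance = 1e-12)
  expect_equal(aicc(2.5, 10, 3), -3.862944, tolerance = 1e-6)
  ## symmetry: identical inputs give identical values
  expect_equal(aicc(c(1.2, 0.8), c(20, 15), 4), aicc(c(1.2, 0.8), c(20, 15), 4))
  ## monotone complexity penalty at fixed RSS and n
  vals <- vapply(1:7, function(k) aicc(2, 10, k), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(aicc(2, 5, 4), "n = 5")
  expect_error(aicc(-1, 10, 2), "positive")
})

test_that("Akaike weights normalize, order and survive extremes", {
  expect_equal(akaike_weights(c(100, 100, 100)), rep(1 / 3, 3))
  w <- akaike_weights(c(10, 12))
  expect_equal(unname(w), c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(akaike_weights(5), 1)
  ## huge differences do not underflow to NaN
  w2 <- akaike_weights(c(0, 5000, 10000))
  expect_equal(sum(w2), 1)
  expect_true(all(is.finite(w2)))
  ## infinite AICc gets zero weight; -Inf takes all of it
  expect_equal(unname(akaike_weights(c(1, Inf))), c(1, 0))
  expect_equal(unname(akaike_weights(c(-Inf, 3))), c(1, 0))
})

test_that("interpolation is exact at training nodes and linear between them", {
  td <- toy_dataset()
  d <- td$design
  for (i in c(2, 8, 13)) {
    v <- interpolate_training_data(td, c(d$dose_1[i], d$dose_2[i]))
    expect_equal(v$value, unname(td$y_smooth[i, ]), tolerance = 1e-9)
    expect_false(v$extrapolated)
  }
  ## 1-D linearity on a collinear two-point configuration
  interp <- awmpc:::dose_interpolant(rbind(c(0, 0), c(10, 0)))
  iw <- awmpc:::interp_weights(interp, c(5, 0))
  vals <- c(0.2, 0.6)
  expect_equal(sum(iw$w * vals[iw$idx]), 0.4, tolerance = 1e-12)
  ## off-line queries on a degenerate configuration are rejected helpfully
  expect_error(awmpc:::interp_weights(interp, c(5, 3)), "degenerate")
})

test_that("queries outside the training hull clamp to the nearest hull point", {
  pts <- rbind(c(1, 1), c(4, 1), c(4, 4), c(1, 4), c(2.5, 2.5))
  interp <- awmpc:::dose_interpolant(pts)
  vals <- c(0.1, 0.5, 0.9, 0.3, 0.6)
  q <- c(5.5, 2.3)                      # outside, nearest hull point (4, 2.3)
  iw <- awmpc:::interp_weights(interp, q)
  expect_true(iw$extrapolated)
  got <- sum(iw$w * vals[iw$idx])
  ## oracle: explicit nearest point on the hull boundary, then barycentric
  ## interpolation along the boundary edge (4,1)-(4,4)
  lam <- (2.3 - 1) / 3
  expect_equal(got, (1 - lam) * vals[2] + lam * vals[3], tolerance = 1e-9)
})

test_that("plant-generated zero-noise data drive the plant's weight to one", {
  bank <- toy_bank()
  td0 <- simulate_training_data(bank$models$C, noise_sd = 0, seed = 1)
  wm <- build_weight_map(bank$models, td0)
  d <- td0$design
  for (i in seq_len(nrow(d))) {
    w <- wm$weight_fn(c(d$dose_1[i], d$dose_2[i]))
    expect_gt(w[["C"]], 0.99)
  }
})

test_that("weights sum to one across random queries and windows", {
  bank <- toy_bank()
  wm <- build_weight_map(bank$models[c("A", "B")], toy_dataset())
  set.seed(42)
  for (i in 1:100) {
    u <- c(runif(1, 0, 50), runif(1, 0, 10))
    expect_equal(sum(wm$weight_fn(u)), 1, tolerance = 1e-9)
  }
  expect_equal(sum(wm$weight_fn(c(20, 3), window = c(13, 18))), 1,
               tolerance = 1e-9)
})

test_that("uninformative data give a flat equal-weight map", {
  bank <- toy_bank()
  td <- toy_dataset()
  ## two copies of the same model: equal fit, equal k -> 1/2 everywhere
  twin <- bank$models$A
  twin$model_id <- "A2"
  wm <- build_weight_map(list(bank$models$A, twin), td)
  set.seed(9)
  for (i in 1:20) {
    u <- c(runif(1, 0, 50), runif(1, 0, 10))
    expect_equal(unname(wm$weight_fn(u)), c(0.5, 0.5), tolerance = 1e-6)
  }
})

test_that("more training data weakly sharpen the plant's maximum weight", {
  bank <- toy_bank()
  plant <- bank$models$C
  members <- bank$models
  peak_w <- vapply(c(10, 31), function(np) {
    td <- simulate_training_data(plant, noise_sd = 0.05, n_timepoints = np,
                                 seed = 6)
    wm <- build_weight_map(members, td)
    g <- expand.grid(u1 = seq(0, 50, length.out = 5),
                     u2 = seq(0, 10, length.out = 5))
    max(apply(g, 1, function(u) wm$weight_fn(as.numeric(u))[["C"]]))
  }, numeric(1))
  expect_gte(peak_w[2], peak_w[1] - 1e-9)
})

test_that("model rankings are robust between full and limited datasets", {
  bank <- toy_bank()
  plant <- bank$models$C
  full <- simulate_training_data(plant, noise_sd = 0.05, n_timepoints = 31,
                                 seed = 1)
  lim <- simulate_training_data(plant, noise_sd = 0.05, n_timepoints = 10,
                                seed = 1)
  wm_f <- build_weight_map(bank$models[c("A", "B")], full)
  wm_l <- build_weight_map(bank$models[c("A", "B")], lim)
  expect_gte(ranking_agreement(wm_f, wm_l, n1 = 7, n2 = 7), 0.8)
})

test_that("weight-map JSON export is lattice-complete", {
  bank <- toy_bank()
  wm <- build_weight_map(bank$models[c("A", "B")], toy_dataset())
  path <- tempfile(fileext = ".json")
  out <- export_weight_map(wm, path, n1 = 5, n2 = 4)
  expect_true(file.exists(path))
  expect_equal(dim(out$weights), c(20, 2))
  expect_equal(rowSums(out$weights), rep(1, 20), tolerance = 1e-9)
})
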