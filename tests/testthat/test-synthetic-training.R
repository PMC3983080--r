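test_that("the screening design matches the 14-experiment protocol", {
  d <- generate_training_design()
  expect_equal(nrow(d), 14)
  u1_only <- d$dose_1 > 0 & d$dose_2 == 0
  expect_true(all(d$dose_time_min[u1_only] == 15))
  u2_rows <- d$dose_2 > 0
  expect_true(all(d$dose_time_min[u2_rows] == 6))
  space <- input_space()
  expect_true(all(d$dose_1 >= 0 & d$dose_1 <= space$upper[1]))
  expect_true(all(d$dose_2 >= 0 & d$dose_2 <= space$upper[2]))
  expect_setequal(d$dose_1[u1_only], c(0.5, 2, 5, 20, 50))
})

test_that("zero noise reproduces the plant trajectory exactly", {
  bank <- toy_bank()
  td <- simulate_training_data(bank$models$C, noise_sd = 0,
                               n_timepoints = 8, seed = 3)
  for (e in td$experiments) expect_equal(e$y_raw, e$y_true)
})

test_that("seeding is reproducible and seeds differ", {
  bank <- toy_bank()
  t1 <- simulate_training_data(bank$models$A, n_timepoints = 8, seed = 11)
  t2 <- simulate_training_data(bank$models$A, n_timepoints = 8, seed = 11)
  t3 <- simulate_training_data(bank$models$A, n_timepoints = 8, seed = 12)
  expect_identical(t1$y_smooth, t2$y_smooth)
  expect_false(identical(t1$experiments[[2]]$y_raw,
                         t3$experiments[[2]]$y_raw))
})

test_that("raw measurement counting follows the design", {
  bank <- toy_bank()
  td <- simulate_training_data(bank$models$B, n_timepoints = 8, seed = 2)
  expect_equal(td$n_total, 14 * 8)
})

test_that("smoothing resamples to 31 points spanning the raw range", {
  e <- list(t_samples = seq(0, 30, length.out = 9),
            y_raw = sin(seq(0, 3, length.out = 9)))
  s <- smooth_resample(e)
  expect_length(s$y, 31)
  expect_equal(range(s$t), c(0, 30))
})

test_that("smoothing preserves constants and interpolates at p = 1", {
  tt <- seq(0, 30, length.out = 10)
  const <- list(t_samples = tt, y_raw = rep(0.7, 10))
  expect_equal(smooth_resample(const)$y, rep(0.7, 31), tolerance = 1e-9)
  set.seed(5)
  wig <- list(t_samples = tt, y_raw = runif(10))
  s1 <- smooth_resample(wig, p = 1)
  expect_lt(max(abs(s1$fitted - wig$y_raw)), 1e-8)
  ## p = 0 collapses to the least-squares line
  s0 <- smooth_resample(wig, p = 0)
  line <- stats::lm(wig$y_raw ~ tt)
  expect_equal(unname(s0$fitted),
               unname(stats::fitted(line)), tolerance = 1e-8)
})

test_that("the csaps objective is actually minimized at p = 0.6", {
  ## oracle: direct numerical minimization of the penalized criterion over
  ## natural cubic splines parameterized by their knot values
  set.seed(7)
  tt <- seq(0, 10, length.out = 8)
  y <- sin(tt / 2) + rnorm(8, sd = 0.2)
  p <- 0.6
  crit <- function(f) {
    sp <- stats::splinefun(tt, f, method = "natural")
    rough <- stats::integrate(function(x) sp(x, deriv = 2)^2, 0, 10,
                              subdivisions = 400)$value
    p * sum((y - f)^2) + (1 - p) * rough
  }
  fit <- smooth_resample(list(t_samples = tt, y_raw = y), p = p)$fitted
  opt <- stats::optim(y, crit, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_lt(crit(fit), crit(opt$par) + 1e-6)
  expect_equal(fit, opt$par, tolerance = 1e-3)
})

test_that("smoothed curves approach the noiseless trajectory as noise vanishes", {
  ## measured after the activation rise: the spline's bias at the sharp
  ## 0 -> 1 rise is a property of smoothing, not of the noise level
  bank <- toy_bank()
  plant <- bank$models$C
  sup <- vapply(c(0.1, 0.02, 0), function(sd) {
    td <- simulate_training_data(plant, noise_sd = sd, n_timepoints = 16,
                                 seed = 4)
    truth <- simulate_model(plant, bolus_schedule(), td$t_smooth)$z[, 1]
    sel <- td$t_smooth >= 5
    max(abs(td$y_smooth["control", sel] - truth[sel]))
  }, numeric(1))
  expect_true(all(diff(sup) < 0))
})

test_that("the CSV round trip preserves raw data and counts", {
  bank <- toy_bank()
  td <- simulate_training_data(bank$models$C, n_timepoints = 8, seed = 1)
  path <- tempfile(fileext = ".csv")
  write_training_csv(td, path)
  back <- read_training_csv(path)
  expect_equal(back$n_total, td$n_total)
  expect_equal(back$experiments[[3]]$y_raw, td$experiments[[3]]$y_raw,
               tolerance = 1e-9)
  expect_equal(back$y_smooth[3, ], unname(td$y_smooth[3, ]),
               tolerance = 1e-7, ignore_attr = TRUE)
})
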