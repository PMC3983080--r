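test_that("zero-dose schedules reproduce the uncontrolled trajectory", {
  bank <- toy_bank()
  tg <- seq(0, 30, 0.5)
  for (m in bank$models) {
    unc <- simulate_model(m, bolus_schedule(), tg)
    zero <- simulate_model(m, bolus_schedule(c(3, 13), rbind(c(0, 0), c(0, 0))),
                           tg)
    expect_identical(unc$z, zero$z)
  }
})

test_that("a bolus at 13 min leaves the earlier trajectory bitwise unchanged", {
  bank <- toy_bank()
  tg <- seq(0, 30, 0.5)
  for (m in bank$models) {
    unc <- simulate_model(m, bolus_schedule(), tg)
    dosed <- simulate_model(m, bolus_schedule(13, c(20, 2)), tg)
    pre <- tg < 13
    expect_identical(unc$z[pre, ], dosed$z[pre, ])
    expect_false(isTRUE(all.equal(unc$z[!pre, ], dosed$z[!pre, ])))
  }
})

test_that("mass-action members conserve phospho + unphospho tier totals", {
  bank <- toy_bank()
  tg <- seq(0, 30, 0.5)
  sched <- bolus_schedule(c(6, 15), rbind(c(5, 1), c(20, 0)))
  for (id in c("A", "B")) {
    st <- simulate_model(bank$models[[id]], sched, tg)$states
    for (tier in 1:3) {
      tot <- st[, paste0("X", tier)] + st[, paste0("X", tier, "p")]
      expect_lt(max(abs(tot - 1)), 1e-6)
    }
  }
})

test_that("states stay nonnegative under schedules across the input space", {
  bank <- toy_bank()
  tg <- seq(0, 30, 0.5)
  for (m in bank$models) {
    for (u in list(c(0, 0), c(50, 0), c(0, 10), c(50, 10), c(5, 1))) {
      st <- simulate_model(m, bolus_schedule(6, u), tg)$states
      expect_gt(min(st), -1e-9)
    }
  }
})

test_that("calibration scales the uncontrolled peak to unity and is idempotent", {
  bank <- make_toy_bank(calibrate = FALSE)
  for (m in bank$models) {
    cal <- calibrate_normalization(m)
    unc <- simulate_model(cal, bolus_schedule())
    expect_equal(max(unc$z), 1, tolerance = 1e-6)
    cal2 <- calibrate_normalization(cal)
    expect_equal(cal$output_scale, cal2$output_scale, tolerance = 1e-9)
  }
})

test_that("calibration is invariant to rescaling of the raw output map", {
  bank <- make_toy_bank(calibrate = FALSE)
  m <- bank$models$A
  m7 <- m
  raw_map <- m$controlled_map
  m7$controlled_map <- function(x, u, t, p) 7 * raw_map(x, u, t, p)
  m7$measured_map <- m7$controlled_map
  z1 <- simulate_model(calibrate_normalization(m), bolus_schedule(6, c(5, 1)))$z
  z7 <- simulate_model(calibrate_normalization(m7), bolus_schedule(6, c(5, 1)))$z
  expect_equal(z1, z7, tolerance = 1e-8)
})

test_that("compiled and R dynamics agree", {
  bank <- toy_bank()
  sched <- bolus_schedule(c(6, 15), rbind(c(10, 1), c(5, 0.5)))
  for (m in bank$models) {
    mR <- m
    mR$csym <- NULL
    zc <- simulate_model(m, sched, 0:30)$z
    zr <- simulate_model(mR, sched, 0:30)$z
    expect_equal(zc, zr, tolerance = 1e-7)
  }
})

test_that("the bank reproduces the qualitative dose-response trends", {
  bank <- toy_bank()
  tg <- seq(0, 30, 0.5)
  for (m in bank$models) {
    unc <- simulate_model(m, bolus_schedule(), tg)
    hi1 <- simulate_model(m, bolus_schedule(15, c(50, 0)), tg)
    lo2 <- simulate_model(m, bolus_schedule(6, c(0, 0.5)), tg)
    both <- simulate_model(m, bolus_schedule(6, c(50, 10)), tg)
    only1 <- simulate_model(m, bolus_schedule(6, c(50, 0)), tg)
    only2 <- simulate_model(m, bolus_schedule(6, c(0, 10)), tg)
    last <- length(tg)
    ## phosphatase inhibition elevates/sustains the late response
    expect_gt(hi1$z[last], unc$z[last])
    ## kinase inhibition bites within 2 min even at the lowest tested dose
    dz <- diff(lo2$z[, 1])[tg[-1] > 6 & tg[-1] <= 8.01]
    expect_true(any(dz < 0))
    ## the kinase inhibitor overpowers the phosphatase inhibitor combined
    expect_lt(abs(both$z[last] - only2$z[last]),
              abs(both$z[last] - only1$z[last]))
  }
})

test_that("bank members are structurally distinct in their responses", {
  bank <- toy_bank()
  tg <- seq(0, 30, 1)
  g <- expand.grid(u1 = seq(0, 50, length.out = 5),
                   u2 = seq(0, 10, length.out = 5))
  zs <- lapply(bank$models, function(m) {
    vapply(seq_len(nrow(g)), function(i) {
      u <- as.numeric(g[i, ])
      sched <- if (all(u == 0)) bolus_schedule() else bolus_schedule(6, u)
      simulate_model(m, sched, tg)$z[, 1]
    }, numeric(length(tg)))
  })
  pairs <- combn(3, 2)
  for (p in seq_len(ncol(pairs))) {
    d <- sqrt(colSums((zs[[pairs[1, p]]] - zs[[pairs[2, p]]])^2))
    expect_gt(max(d), 0.1)
  }
})

test_that("schedule and space validation reject malformed inputs", {
  expect_error(bolus_schedule(c(5, 3), rbind(c(1, 1), c(1, 1))),
               "increasing")
  expect_error(bolus_schedule(5, c(60, 0)), "bounds")
  expect_error(input_space(c(1, 1), c(0, 2)), "componentwise")
  ## integration failure diagnostics name the model
  bad <- prediction_model("bad", c(x = 1), c(k = 1),
                          rhs = function(x, u, t, p) x^2 * 1e6,
                          measured_map = function(x, u, t, p) x[[1]],
                          controlled_map = function(x, u, t, p) x[[1]],
                          n_u = 2)
  suppressWarnings(
    expect_error(simulate_model(bad, bolus_schedule(), seq(0, 30, 1)), "bad"))
})

test_that("tidy export is long-format and complete", {
  bank <- toy_bank()
  res <- simulate_model(bank$models$C, bolus_schedule(), 0:10)
  df <- tidy_simulation(res, what = "z")
  expect_named(df, c("model_id", "time_min", "variable", "value"))
  expect_equal(nrow(df), 11)
})
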