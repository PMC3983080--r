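## a lighter configuration keeps the controller tests fast; the full-size
## study conditions are exercised by the benchmark suite
fast_cfg <- function(...) {
  run_config(n_pareto = 6, max_depth = 5, ...)
}

test_that("the open-loop sequence has one dose per dosing interval", {
  bank <- toy_bank()
  useq <- run_open_loop(bank$models["C"], NULL,
                        target_trajectory(22, 0), fast_cfg(), w_fixed = 1)
  expect_equal(nrow(useq$doses), 5)
  expect_equal(useq$dose_times, c(3, 8, 13, 18, 23))
  space <- input_space()
  expect_true(all(useq$doses >= -1e-9))
  expect_true(all(t(useq$doses) <= space$upper + 1e-9))
})

test_that("tracking the plant's own uncontrolled trajectory needs no dosing", {
  bank <- toy_bank()
  plant <- bank$models$C
  tg <- seq(0, 30, 0.25)
  unc <- simulate_model(plant, bolus_schedule(), tg)
  target <- curve_target(tg, unc$z[, 1])
  useq <- run_open_loop(bank$models["C"], NULL, target, fast_cfg(),
                        w_fixed = 1)
  space <- input_space()
  for (j in 1:2) {
    expect_true(all(useq$doses[, j] < 0.05 * space$upper[j]))
  }
})

test_that("open-loop design is deterministic", {
  bank <- toy_bank()
  td <- toy_dataset()
  wm <- build_weight_map(bank$models[c("A", "B")], td)
  target <- target_trajectory(15, 0.25)
  u1 <- run_open_loop(bank$models[c("A", "B")], wm, target, fast_cfg())
  u2 <- run_open_loop(bank$models[c("A", "B")], wm, target, fast_cfg())
  expect_identical(u1$doses, u2$doses)
  expect_identical(u1$weights, u2$weights)
})

test_that("plant application reproduces limiting cases", {
  bank <- toy_bank()
  plant <- bank$models$C
  target <- target_trajectory(22, 0)
  zero <- list(doses = matrix(0, 5, 2), dose_times = dosing_times())
  ap <- apply_to_plant(plant, zero, target)
  unc <- simulate_model(plant, bolus_schedule(), seq(0, 30, 1))
  expect_equal(ap$z, unc$z[, 1], tolerance = 1e-9)
  expect_gte(ap$sq_error, 0)
  ## a trajectory equal to the target scores zero
  tg <- seq(0, 30, 1)
  self_target <- curve_target(tg, ap$z)
  ap2 <- apply_to_plant(plant, zero, self_target)
  expect_equal(ap2$sq_error, 0, tolerance = 1e-12)
})

test_that("the matched controller never loses to leaving the plant alone", {
  bank <- toy_bank()
  plant <- bank$models$C
  cfg <- fast_cfg()
  zero <- list(doses = matrix(0, 5, 2), dose_times = dosing_times())
  for (i in c(1, 5, 10)) {               # spot-check across the preset
    ps <- target_preset()
    target <- target_trajectory(ps$t_off[i], ps$p_ss[i])
    useq <- run_open_loop(bank$models["C"], NULL, target, cfg, w_fixed = 1)
    ctl <- apply_to_plant(plant, useq, target)
    unc <- apply_to_plant(plant, zero, target)
    expect_lte(ctl$sq_error, unc$sq_error + 1e-6)
  }
})

test_that("surrogate and direct-evaluation controllers are interchangeable", {
  ## the tracking objective has wide flat valleys (many doses are
  ## near-equivalent), so the two modes may park far apart in input space;
  ## interchangeability means the chosen inputs are objective-equivalent
  bank <- toy_bank()
  target <- target_trajectory(22, 0)
  sp <- objective_spec()
  space <- input_space()
  u_s <- run_open_loop(bank$models["B"], NULL, target,
                       fast_cfg(use_surrogate = TRUE), w_fixed = 1)
  u_d <- run_open_loop(bank$models["B"], NULL, target,
                       fast_cfg(use_surrogate = FALSE), w_fixed = 1)
  ## interval 1: identical starting states, so the direct objective can
  ## compare the two committed doses head to head
  j_s <- tracking_objective(bank$models$B, NULL, u_s$doses[1, ], target, sp,
                            c(3, 8), space)
  j_d <- tracking_objective(bank$models$B, NULL, u_d$doses[1, ], target, sp,
                            c(3, 8), space)
  expect_lt(abs(j_s - j_d), 0.15)
  ## realized performance on the plant stays comparable end to end
  a_s <- apply_to_plant(bank$models$C, u_s, target)
  a_d <- apply_to_plant(bank$models$C, u_d, target)
  expect_lt(abs(a_s$sq_error - a_d$sq_error),
            0.5 + 0.35 * max(a_s$sq_error, a_d$sq_error))
})

test_that("weight-map sensitivity report satisfies its identities", {
  bank <- toy_bank()
  td <- toy_dataset()
  wm <- build_weight_map(bank$models[c("A", "B")], td)
  ## identical datasets agree perfectly and give identical sequences
  rep1 <- weight_map_sensitivity(bank$models[c("A", "B")], td, td,
                                 targets = data.frame(t_off = 22, p_ss = 0),
                                 cfg = fast_cfg(), n1 = 5, n2 = 5)
  expect_equal(rep1$agreement, 1)
  expect_equal(rep1$dose_diff, 0)
  ## the agreement metric is symmetric
  lim <- simulate_training_data(bank$models$C, noise_sd = 0.05,
                                n_timepoints = 10, seed = 1)
  wl <- build_weight_map(bank$models[c("A", "B")], lim)
  expect_equal(ranking_agreement(wm, wl, n1 = 5, n2 = 5),
               ranking_agreement(wl, wm, n1 = 5, n2 = 5))
})

test_that("control sequences export to CSV and JSON", {
  useq <- list(doses = matrix(c(1, 2, 0, 3), 2, 2),
               dose_times = c(3, 8))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".json")
  write_control_sequence(useq, p1)
  write_control_sequence(useq, p2)
  back <- utils::read.csv(p1)
  expect_equal(back$u1, c(1, 2))
  expect_equal(back$u2, c(0, 3))
  expect_true(file.exists(p2))
})

test_that("run configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("upper: [50, 10]", "n_pareto: 9", "windowed: false",
               "targets:", "  - [22, 0]", "  - [8, 0.5]"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$n_pareto, 9)
  expect_false(cfg$windowed)
  tg <- attr(cfg, "targets")
  expect_equal(tg$t_off, c(22, 8))
  expect_equal(tg$p_ss, c(0, 0.5))
})
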