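test_that("target trajectories have the documented shape", {
  ## no-turn-off sustained-maximal case holds near 1 after the rise
  r <- target_trajectory(30, 1)
  expect_true(all(abs(r$value_fn(seq(5, 30, 0.5)) - 1) < 0.01))
  ## full termination decays monotonically past the turn-off
  r2 <- target_trajectory(8, 0)
  v <- r2$value_fn(seq(9, 30, 0.25))
  expect_true(all(diff(v) <= 1e-12))
  ## steady state attained by 30 min for every preset pair with t_off <= 22
  ps <- target_preset()
  for (i in which(ps$t_off <= 22)) {
    r3 <- target_trajectory(ps$t_off[i], ps$p_ss[i])
    expect_lt(abs(r3$value_fn(30) - ps$p_ss[i]), 0.01)
  }
  expect_equal(nrow(ps), 10)
  expect_error(target_trajectory(0, 0.5), "t_off")
  expect_error(target_trajectory(10, 1.2), "p_ss")
})

test_that("the tracking objective matches hand arithmetic", {
  ## scalar case: one horizon sample, zhat = 0.5, r = 1, u = 0.2,
  ## Q = R = 1, unit input bounds -> J = 0.25 + 0.04 = 0.29
  m <- prediction_model("const", c(x = 0.5), c(k = 0),
                        rhs = function(x, u, t, p) 0,
                        measured_map = function(x, u, t, p) x[[1]],
                        controlled_map = function(x, u, t, p) x[[1]],
                        n_u = 1)
  sp <- objective_spec(Q = 1, R = 1, dt_sample = 1)
  space1 <- input_space(0, 1)
  target1 <- curve_target(c(0, 40), c(1, 1))
  J <- tracking_objective(m, state = NULL, u_k = 0.2, target = target1,
                          spec = sp, interval = c(0, 1), space = space1)
  expect_equal(J, log(0.29 + 1e-12), tolerance = 1e-9)
  ## perfect tracking at zero dose returns ln(log_eps)
  target0 <- curve_target(c(0, 40), c(0.5, 0.5))
  J0 <- tracking_objective(m, NULL, 0, target0, sp, c(0, 1), space1)
  expect_equal(J0, log(1e-12), tolerance = 1e-6)
  ## Q = 0 leaves only the control-effort term
  spQ0 <- objective_spec(Q = 0, R = 1, dt_sample = 1)
  JQ0 <- tracking_objective(m, NULL, 0.2, target1, spQ0, c(0, 1), space1)
  expect_equal(JQ0, log(0.04 + 1e-12), tolerance = 1e-9)
})

test_that("objective surrogates agree with direct evaluation", {
  bank <- toy_bank()
  target <- target_trajectory(22, 0)
  sp <- objective_spec()
  space <- input_space()
  fns <- build_objective_surrogates(bank$models["C"], list(NULL), target, sp,
                                    interval = c(3, 8), space = space)
  s <- attr(fns[[1]], "surrogate")
  lo <- space$lower
  wid <- space$upper - lo
  for (i in seq_len(nrow(s$node_set))) {
    u <- lo + s$node_set[i, ] * wid
    direct <- tracking_objective(bank$models$C, NULL, u, target, sp,
                                 c(3, 8), space)
    expect_equal(fns[[1]](u), direct, tolerance = 1e-9)
  }
  ## disabled-surrogate mode returns a callable with the same contract
  fd <- build_objective_surrogates(bank$models["C"], list(NULL), target, sp,
                                   interval = c(3, 8), space = space,
                                   use_surrogate = FALSE)
  u <- c(10, 2)
  expect_equal(fd[[1]](u),
               tracking_objective(bank$models$C, NULL, u, target, sp,
                                  c(3, 8), space))
})

test_that("surrogate argmin matches brute-force lattice argmin", {
  bank <- toy_bank()
  sp <- objective_spec()
  space <- input_space()
  g1 <- seq(0, 50, length.out = 21)
  g2 <- seq(0, 10, length.out = 21)
  grid <- as.matrix(expand.grid(g1, g2))
  sweep_one <- function(id, interval, t_off, p_ss) {
    target <- target_trajectory(t_off, p_ss)
    fns <- build_objective_surrogates(bank$models[id], list(NULL), target,
                                      sp, interval = interval, space = space)
    sv <- apply(grid, 1, function(u) fns[[1]](u))
    dv <- apply(grid, 1, function(u)
      tracking_objective(bank$models[[id]], NULL, u, target, sp, interval,
                         space))
    expect_true(all(is.finite(sv)))
    expect_true(all(is.finite(dv)))
    list(sv = sv, dv = dv)
  }
  ## a scenario with a well-separated optimum: strict one-cell agreement
  r <- sweep_one("C", c(23, 28), 22, 0)
  expect_lte(abs(grid[which.min(r$sv), 1] - grid[which.min(r$dv), 1]), 2.5)
  expect_lte(abs(grid[which.min(r$sv), 2] - grid[which.min(r$dv), 2]), 0.5)
  ## a scenario with a flat cost valley: the surrogate's argmin must be
  ## objective-equivalent to the true argmin even if it sits elsewhere
  ## in the valley
  r2 <- sweep_one("B", c(13, 18), 15, 0.25)
  expect_lte(r2$dv[which.min(r2$sv)] - min(r2$dv), 0.05)
})
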