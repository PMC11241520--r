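test_that("S statistic matches its printed formula", {
  expect_equal(rmse_s(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_s(c(0, 0), c(1, 1), n_params = 0), 1)
  # independent brute-force summation on fixed pseudo-random series
  set.seed(42)
  ye <- rnorm(40); ys <- rnorm(40)
  acc <- 0
  for (i in seq_along(ye)) acc <- acc + (ye[i] - ys[i])^2
  expect_equal(rmse_s(ye, ys, n_params = 3), sqrt(acc / 37),
               tolerance = 1e-12)
  # permutation invariance
  perm <- sample(40)
  expect_equal(rmse_s(ye[perm], ys[perm], 3), rmse_s(ye, ys, 3))
  expect_error(rmse_s(1:3, 1:4), "equal length")
  expect_error(rmse_s(1:3, 2:4, n_params = 3), "degrees-of-freedom")
})

test_that("goodness-of-fit verdict uses a strict 5%-of-range threshold", {
  expect_true(gof_pass(0, 100)$passed)
  expect_equal(gof_pass(1, 100)$threshold, 5)
  expect_true(gof_pass(4.999, 100)$passed)
  expect_false(gof_pass(5, 100)$passed)      # boundary fails (strict)
  expect_false(gof_pass(6, 100)$passed)
  expect_error(gof_pass(1, 0), "degenerate")
})

test_that("Hill fit recovers known parameters from clean data", {
  d <- simulate_activation_curve(n = 30, ca_half = 1e-3, hill_n = 2,
                                 noise_sd = 0, seed = 7)
  fit <- fit_hill(d)
  expect_equal(fit$ca_half, 1e-3, tolerance = 0.01)
  expect_equal(fit$hill_n, 2, tolerance = 0.01)
  expect_lt(fit$report$S, 1e-6)
  expect_true(fit$report$passed)
})

test_that("Hill fit parameter recovery across 20 seeded noisy datasets", {
  scen <- expand.grid(ca_half = 10^seq(-4, -2, length.out = 5),
                      hill_n = c(1, 2, 3, 4))
  rel <- mapply(function(ch, n, seed) {
    d <- simulate_activation_curve(n = 30, ca_half = ch, hill_n = n,
                                   noise_sd = 0.02, seed = seed)
    fit <- fit_hill(d)
    abs(fit$ca_half - ch) / ch
  }, scen$ca_half, scen$hill_n, seq_len(nrow(scen)))
  expect_lt(median(rel), 0.05)
})

test_that("gof verdict holds at recovered parameters under 0.02 noise", {
  d <- simulate_activation_curve(n = 30, ca_half = 1e-3, hill_n = 2,
                                 noise_sd = 0.02, seed = 11)
  fit <- fit_hill(d)
  expect_true(fit$report$passed)
})

test_that("degenerate activation datasets are rejected", {
  expect_error(fit_hill(data.frame(cai = 1e-3, activation = 0.5)),
               "3 data points")
  expect_error(fit_hill(data.frame(cai = c(-1, 1, 2), activation = c(0, 1, 1))),
               "positive")
})

test_that("calibration recovers a conductance on a two-channel toy model", {
  # toy: K-like leak vs depolarizing background; analytic rest
  # v = (gK eK + gB eB)/(gK + gB); target -52 with eK=-75, eB=0, gB=1e-4
  # requires gK = gB * (0 - (-52)) / ((-52) - (-75)) = 1e-4 * 52/23
  target_gk <- 1e-4 * 52 / 23
  m <- two_leak_model(g1 = 1.9e-4, e1 = -75, g2 = 1e-4, e2 = 0)
  cal <- calibrate_cell(m, targets = list(rmp = -52), channels = "k",
                        bound = 0.3, grid_points = 7, passes = 3,
                        measure_opts = list(t_stop = 400))
  expect_true(cal$converged)
  expect_equal(channel_gmax(cal$model, "k"), target_gk, tolerance = 0.02)
  expect_equal(cal$report$after[cal$report$target == "rmp"], -52,
               tolerance = 0.5, ignore_attr = TRUE)
})

test_that("calibration already at target is the identity", {
  gk <- 1e-4 * 52 / 23
  m <- two_leak_model(g1 = gk, e1 = -75, g2 = 1e-4, e2 = 0)
  cal <- calibrate_cell(m, targets = list(rmp = -52), channels = "k",
                        bound = 0.3, grid_points = 5, passes = 1,
                        measure_opts = list(t_stop = 400))
  expect_equal(channel_gmax(cal$model, "k"), gk)
})

test_that("calibration never leaves the declared bounds", {
  # unreachable target: rest of -10 mV cannot be met within +/-30%
  m <- two_leak_model(g1 = 2e-4, e1 = -75, g2 = 1e-4, e2 = 0)
  cal <- calibrate_cell(m, targets = list(rmp = -10), channels = c("k", "bg"),
                        bound = 0.3, grid_points = 5, passes = 2,
                        measure_opts = list(t_stop = 400))
  expect_false(cal$converged)
  expect_gte(channel_gmax(cal$model, "k"), 2e-4 * 0.7 - 1e-12)
  expect_lte(channel_gmax(cal$model, "k"), 2e-4 * 1.3 + 1e-12)
  expect_gte(channel_gmax(cal$model, "bg"), 1e-4 * 0.7 - 1e-12)
  expect_lte(channel_gmax(cal$model, "bg"), 1e-4 * 1.3 + 1e-12)
})
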