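test_that("Boltzmann steady state: midpoint, saturation, monotonicity", {
  act <- gate_params("boltzmann", v_half = 38, slope = -8)
  expect_equal(boltzmann_inf(-38, act), 0.5)
  # printed-form check: at v = -30, (v + 38)/-8 = -1 -> 1/(1 + e^-1)
  expect_equal(boltzmann_inf(-30, act), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(boltzmann_inf(-1e4, act), 0, tolerance = 1e-12)
  expect_equal(boltzmann_inf(1e4, act), 1, tolerance = 1e-12)
  v <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(boltzmann_inf(v, act)) > 0))
  inact <- gate_params("boltzmann", v_half = 38, slope = 8)
  expect_true(all(diff(boltzmann_inf(v, inact)) < 0))
  expect_true(all(boltzmann_inf(v, act) > 0 & boltzmann_inf(v, act) < 1))
})

test_that("gate_step is the exact first-order relaxation", {
  g <- gate_params("boltzmann", v_half = 40, slope = -6, tau = 1)
  # fixed point
  minf <- boltzmann_inf(-30, g)
  expect_equal(gate_step(minf, -30, g, dt = 0.7), minf)
  # closed form from m = 0: 1 - e^(-dt/tau)
  g1 <- gate_params("boltzmann", v_half = 1e6, slope = -1, tau = 1)  # minf ~ 1
  expect_equal(gate_step(0, 0, g1, dt = 1), 1 - exp(-1), tolerance = 1e-9)
  # relaxation limit
  expect_equal(gate_step(0.1, -30, g, dt = 1e6), minf, tolerance = 1e-12)
})

test_that("gate_step agrees with a fine-step Euler oracle", {
  gate <- gate_params("boltzmann", v_half = 36, slope = -6, tau = 4)
  for (v in c(-70, -50, -30, 0)) {
    for (m0 in c(0, 0.3, 0.9)) {
      minf <- boltzmann_inf(v, gate)
      oracle <- euler_gate(m0, minf, tau = 4, dt = 0.4, n_sub = 40000)
      expect_close(gate_step(m0, v, gate, dt = 0.4), oracle, 1e-6)
    }
  }
})

test_that("voltage-dependent tau tables interpolate linearly", {
  gate <- gate_params("boltzmann", v_half = 30, slope = -6,
                      tau = list(v = c(-60, -40, -20), tau = c(10, 2, 6)))
  # at v = -50 tau = 6; relaxation factor must match
  minf <- boltzmann_inf(-50, gate)
  got <- gate_step(0.2, -50, gate, dt = 3)
  expect_equal(got, minf + (0.2 - minf) * exp(-3 / 6), tolerance = 1e-12)
  # flat extrapolation beyond the table
  got_lo <- gate_step(0.2, -100, gate, dt = 3)
  minf_lo <- boltzmann_inf(-100, gate)
  expect_equal(got_lo, minf_lo + (0.2 - minf_lo) * exp(-3 / 10),
               tolerance = 1e-12)
})

test_that("invalid gate parameters are rejected", {
  expect_error(gate_params("boltzmann", v_half = 10, slope = 0), "non-zero")
  expect_error(gate_params("boltzmann", v_half = 10, slope = -5, tau = 0),
               "tau")
  expect_error(gate_params("boltzmann", v_half = 10, slope = -5, power = -1),
               "power")
  expect_error(gate_params("hill", ca_half = 0, hill_n = 2), "ca_half")
  expect_error(gate_params("hill",
                           tau = list(v = c(0, -10), tau = c(1, 2)),
                           ca_half = 1e-3, hill_n = 2), "increasing")
})

test_that("hh_current follows the ohmic gated current law", {
  spec <- hh_channel("cal", gmax = 3e-4, e_rev = 50,
                     activation = gate_params("boltzmann", 30, -5))
  # gmax * m * (v - e): published CaL conductance, m = 1, driving -10 mV
  expect_equal(hh_current(spec, m = 1, v = 40), -3.0)
  expect_equal(hh_current(spec, m = 0, v = -60), 0)
  expect_equal(hh_current(spec, m = 0.5, v = 50), 0)  # reversal
  # linear in gmax and driving force
  spec2 <- spec; spec2$gmax <- 6e-4
  expect_equal(hh_current(spec2, m = 0.3, v = 0),
               2 * hh_current(spec, m = 0.3, v = 0))
  expect_equal(hh_current(spec, m = 0.3, v = 30) /
                 hh_current(spec, m = 0.3, v = 40),
               2, tolerance = 1e-12)
  # powers multiply
  spec3 <- hh_channel("x", gmax = 1e-4, e_rev = -75,
                      activation = gate_params("boltzmann", 30, -5, power = 2),
                      inactivation = gate_params("boltzmann", 50, 6))
  expect_equal(hh_current(spec3, m = 0.5, h = 0.25, v = -15),
               1e-4 * 0.25 * 0.25 * 60 * 1e3)
})
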