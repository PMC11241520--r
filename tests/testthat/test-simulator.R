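test_that("passive model matches the analytic RC charging curve", {
  g <- 1e-3 / 138             # S/cm^2 -> tau = 138 ms
  m <- passive_model(e_leak = -52, g_leak = g)
  area <- lateral_area(m$geometry)
  amp <- 0.05                  # nA
  tr <- simulate_cell(m, pulse_stimulus(amp, onset = 0, duration = 400),
                      t_stop = 400, dt = 0.002, v_init = -52,
                      record_every = 50L)
  tau <- 1 / (g * 1e3)                          # ms
  dv_inf <- amp * 1e-3 / area / (g * 1e3)       # steady-state deflection, mV
  analytic <- -52 + dv_inf * (1 - exp(-tr$t / tau))
  expect_lt(max(abs(tr$v - analytic)) / dv_inf, 1e-4)
})

test_that("two-conductance model rests at the conductance-weighted mean", {
  m <- two_leak_model(g1 = 2e-4, e1 = -75, g2 = 1e-4, e2 = 0)
  v_rest <- (2e-4 * -75 + 1e-4 * 0) / 3e-4
  tr <- simulate_cell(m, NULL, t_stop = 100, v_init = -20)
  expect_equal(tail(tr$v, 1), v_rest, tolerance = 1e-6)
})

test_that("a state at its fixed point stays there", {
  m <- two_leak_model()
  v_rest <- -50
  st <- initial_state(m, v0 = v_rest)
  st2 <- step_cell(m, st, NULL, dt = 0.04)
  expect_equal(st2$v, v_rest, tolerance = 1e-9)
  expect_equal(st2$cai, st$cai)
})

test_that("runs are deterministic and prefix-consistent", {
  m <- default_dsm_model()
  tr1 <- simulate_cell(m, pulse_stimulus(0.8, onset = 20), t_stop = 60)
  tr2 <- simulate_cell(m, pulse_stimulus(0.8, onset = 20), t_stop = 60)
  expect_identical(tr1$v, tr2$v)
  expect_identical(tr1$cai, tr2$cai)
  long <- simulate_cell(m, pulse_stimulus(0.8, onset = 20), t_stop = 120)
  n <- nrow(tr1)
  expect_identical(tr1$v, long$v[seq_len(n)])
})

test_that("zero-conductance model holds a flat line at the initial voltage", {
  m <- cell_model(channels = list(leak = hh_channel("leak", 0, -52)),
                  bk = bk_params(gmax = 0), trpm4 = trpm4_params(gmax = 0),
                  calcium = ca_pool_params(clamp = TRUE))
  tr <- simulate_cell(m, NULL, t_stop = 50, v_init = -33)
  expect_true(all(tr$v == -33))
})

test_that("total_membrane_current is additive over channels", {
  m <- default_dsm_model()
  st <- initial_state(m)
  dv <- total_membrane_current(m, st, 0, NULL)
  cur <- attr(dv, "currents")
  # removing one channel changes dV/dt by exactly that channel's current / C
  m2 <- set_channel_gmax(m, "kdr", 0)
  st2 <- st  # same state
  dv2 <- total_membrane_current(m2, st2, 0, NULL)
  expect_equal(as.numeric(dv2 - dv), cur[["kdr"]] /
                 m$passive$c_specific_uF_cm2, tolerance = 1e-12)
  # all-zero conductances, no stimulus: dV/dt = 0
  m0 <- m
  for (ch in channel_names(m0)) m0 <- set_channel_gmax(m0, ch, 0)
  expect_equal(as.numeric(total_membrane_current(m0, st, 0, NULL)), 0)
})

test_that("R-side current balance agrees with the compiled core at rest", {
  m <- default_dsm_model()
  st <- initial_state(m)
  # run 1500 ms to the model's fixed point, then compare |dV/dt|
  tr <- simulate_cell(m, NULL, t_stop = 1500, state = st)
  fs <- attr(tr, "final_state")
  dv <- total_membrane_current(m, fs, 0, NULL)
  expect_lt(abs(as.numeric(dv)), 1e-4)  # mV/ms at the settled point
})

test_that("integration diverging past 200 mV raises a named error", {
  # runaway: strong depolarizing conductance, no brake
  m <- cell_model(channels = list(bg = hh_channel("bg", 5e-3, 400)),
                  bk = bk_params(gmax = 0), trpm4 = trpm4_params(gmax = 0),
                  calcium = ca_pool_params(clamp = TRUE))
  expect_error(simulate_cell(m, NULL, t_stop = 100, v_init = -50),
               "integration failure at step")
})

test_that("self-convergence: halving dt shrinks the trace difference", {
  m <- default_dsm_model()
  st <- initial_state(m)
  # subthreshold pulse keeps the comparison pointwise-meaningful
  stim <- pulse_stimulus(0.3, onset = 20, duration = 10, unit_nA = 0.1)
  run_dt <- function(dt) {
    simulate_cell(m, stim, t_stop = 80, dt = dt, state = st,
                  record_every = as.integer(round(0.16 / dt)))$v
  }
  v1 <- run_dt(0.04)
  v2 <- run_dt(0.02)
  v3 <- run_dt(0.01)
  e1 <- max(abs(v1 - v3))
  e2 <- max(abs(v2 - v3))
  expect_lt(e2, e1)          # smaller dt, smaller error
  expect_lt(e1, 0.5)         # and already sub-0.5 mV at the default dt
})
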