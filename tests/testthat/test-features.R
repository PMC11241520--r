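flat_trace <- function(v0 = -52, t_stop = 800, dt = 0.1) {
  structure(data.frame(t = seq(0, t_stop, by = dt),
                       v = rep(v0, t_stop / dt + 1)),
            class = c("dsm_trace", "data.frame"))
}

test_that("flat trace: RMP reported, no spike", {
  f <- extract_features(flat_trace(-52), onset = Inf)
  expect_false(f$spike_detected)
  expect_equal(f$rmp, -52)
  expect_error(extract_features(flat_trace(-52, t_stop = 300), settle = 500),
               "shorter")
})

test_that("hand-built triangular spike: threshold within one sample", {
  d <- dsmcell:::toy_spike_trace(rest = -52, thr = -38, peak = 10, dt = 0.1,
                                 onset = 600)
  tr <- structure(d, class = c("dsm_trace", "data.frame"))
  f <- extract_features(tr, onset = 600, settle = 500)
  expect_true(f$spike_detected)
  expect_equal(f$rmp, -52)
  expect_equal(f$peak_v, 10)
  # ramp rises at 1 mV/ms (below criterion), fast rise at 20 mV/ms:
  # threshold must sit within one sample of the constructed -38 mV knee
  expect_lt(abs(f$threshold_v - (-38)), 2 * 0.1 * 20 + 1e-9)
  expect_false(f$nonphysiological)
  expect_gt(f$ahp_depth, 0)
  # invariant: peak > threshold > rmp
  expect_true(f$peak_v > f$threshold_v && f$threshold_v > f$rmp)
})

test_that("feature extraction is invariant to a uniform time shift", {
  d <- dsmcell:::toy_spike_trace()
  tr1 <- structure(d, class = c("dsm_trace", "data.frame"))
  d2 <- d; d2$t <- d2$t + 250
  tr2 <- structure(d2, class = c("dsm_trace", "data.frame"))
  f1 <- extract_features(tr1, onset = 600, settle = 500)
  f2 <- extract_features(tr2, onset = 850, settle = 500)
  for (nm in c("rmp", "threshold_v", "peak_v", "ap_duration", "ahp_depth")) {
    expect_equal(f1[[nm]], f2[[nm]], label = nm)
  }
  expect_equal(f2$peak_t - f1$peak_t, 250)
})

test_that("threshold search recovers the analytic rheobase of a leaky toy", {
  # passive leak + hard spike criterion is emulated with the full model by
  # checking the bisection contract instead: returned amplitude spikes,
  # amplitude - resolution does not
  m <- default_dsm_model()
  st <- initial_state(m)
  thr <- threshold_search(m, "pulse", lo = 0.2, hi = 1.4, resolution = 0.02,
                          onset = 200, unit_nA = 0.1, t_stop = 500,
                          state = st, settle = 150)
  probe <- function(amp) {
    tr <- simulate_cell(m, pulse_stimulus(amp, onset = 200, unit_nA = 0.1),
                        t_stop = 500, state = st)
    extract_features(tr, onset = 200, settle = 150)$spike_detected
  }
  expect_true(probe(as.numeric(thr)))
  expect_false(probe(as.numeric(thr) - 0.02))
  # bracket-independence at the same grid
  thr2 <- threshold_search(m, "pulse", lo = as.numeric(thr) - 0.11,
                           hi = as.numeric(thr) + 0.17, resolution = 0.02,
                           onset = 200, unit_nA = 0.1, t_stop = 500,
                           state = st, settle = 150)
  expect_equal(round(as.numeric(thr) / 0.02), round(as.numeric(thr2) / 0.02))
})

test_that("threshold search rejects invalid brackets", {
  m <- default_dsm_model()
  st <- initial_state(m)
  expect_error(threshold_search(m, "pulse", lo = 1.5, hi = 2.0,
                                resolution = 0.01, onset = 100,
                                unit_nA = 0.1, t_stop = 300,
                                state = st, settle = 80),
               "bracket")
  expect_error(threshold_search(m, "pulse", lo = 0.01, hi = 0.05,
                                resolution = 0.01, onset = 100,
                                unit_nA = 0.1, t_stop = 300,
                                state = st, settle = 80),
               "bracket")
})

test_that("sweep normalizes to the factor-1 row and keeps the grid", {
  m <- default_dsm_model()
  sw <- conductance_sweep(m, "trpm4", factors = c(0.9, 1, 1.1),
                          stimulus = default_pulse_protocol(0.8, onset = 300),
                          t_stop = 900)
  expect_equal(nrow(sw), 3)
  ref <- sw[sw$factor == 1, ]
  expect_equal(ref$rmp_norm, 1)
  expect_equal(ref$ap_duration_norm, 1)
  expect_error(conductance_sweep(m, "trpm4", factors = c(0.8, 1.2),
                                 stimulus = pulse_stimulus(0.8)),
               "abs")
})

test_that("knockout of the leak alone leaves a resting, spiking cell", {
  m <- default_dsm_model()
  ko <- knockout_experiment(m, "leak", compensate = NULL,
                            stimulus = default_pulse_protocol(1.2, onset = 300),
                            t_stop = 800)
  expect_true(is.finite(ko$muted$features$rmp))
  expect_error(knockout_experiment(m, "nonesuch", NULL,
                                   pulse_stimulus(1)), "unknown channel")
})
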