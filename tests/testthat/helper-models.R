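# shared fixtures built in code

# passive-only cell: every conductance zero except an ohmic leak
passive_model <- function(e_leak = -52, g_leak = 1e-3 / 138) {
  cell_model(
    geometry = cell_geometry(200, 6),
    passive = passive_properties(1, 138, 183),
    channels = list(leak = hh_channel("leak", gmax = g_leak, e_rev = e_leak)),
    bk = bk_params(gmax = 0),
    trpm4 = trpm4_params(gmax = 0),
    calcium = ca_pool_params(clamp = TRUE)
  )
}

# two-conductance toy with a closed-form resting potential:
# v_rest = (g1 e1 + g2 e2) / (g1 + g2) for two ohmic (gateless) channels
two_leak_model <- function(g1 = 2e-4, e1 = -75, g2 = 1e-4, e2 = 0) {
  cell_model(
    channels = list(k = hh_channel("k", gmax = g1, e_rev = e1),
                    bg = hh_channel("bg", gmax = g2, e_rev = e2)),
    bk = bk_params(gmax = 0),
    trpm4 = trpm4_params(gmax = 0),
    calcium = ca_pool_params(clamp = TRUE)
  )
}

# forward-Euler oracle for a single first-order gate at frozen (v, cai)
euler_gate <- function(m0, minf, tau, dt, n_sub = 1000) {
  h <- dt / n_sub
  m <- m0
  for (i in seq_len(n_sub)) m <- m + h * (minf - m) / tau
  m
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max|diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
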