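# independent spreadsheet-style evaluation of the printed BK rate table
bk_rates_oracle <- function(par, v, cai) {
  a <- exp(v / par$a_efold)
  b <- exp(-v / par$b_efold)
  r <- list()
  r[["C0->C1"]] <- 3 * par$k_on * cai
  r[["C1->C2"]] <- 4 * par$k_on * cai
  r[["C2->C3"]] <- 3 * par$k_on * cai
  r[["C3->C4"]] <- 1 * par$k_on * cai
  r[["C4->C3"]] <- 3 * par$k_coff * cai
  r[["C3->C2"]] <- 4 * par$k_coff * cai
  r[["C2->C1"]] <- 3 * par$k_coff * cai
  r[["C1->C0"]] <- 1 * par$k_coff * cai
  r[["O0->O1"]] <- 3 * par$k_on * cai
  r[["O1->O2"]] <- 4 * par$k_on * cai
  r[["O2->O3"]] <- 3 * par$k_on * cai
  r[["O3->O4"]] <- 1 * par$k_on * cai
  r[["O4->O3"]] <- 3 * par$k_ooff * cai
  r[["O3->O2"]] <- 4 * par$k_ooff * cai
  r[["O2->O1"]] <- 3 * par$k_ooff * cai
  r[["O1->O0"]] <- 1 * par$k_ooff * cai
  co <- c(0.03162, 0.000969, 0.0000381, 0.000881, 0.054324)
  oc <- c(328.1084, 154.1736, 33.6594, 0.097312, 0.000406)
  for (i in 1:5) {
    r[[sprintf("C%d->O%d", i - 1, i - 1)]] <- co[i] * a
    back <- oc[i] * b
    if (i == 5) back <- back * cai
    r[[sprintf("O%d->C%d", i - 1, i - 1)]] <- back
  }
  r
}

test_that("generator matrix reproduces the printed transition table", {
  par <- bk_params()
  for (case in list(c(-52, 1.5e-4), c(0, 0.01), c(30, 0.002))) {
    v <- case[1]; cai <- case[2]
    Q <- bk_rate_matrix(par, v, cai)
    oracle <- bk_rates_oracle(par, v, cai)
    for (nm in names(oracle)) {
      parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
      expect_equal(Q[parts[1], parts[2]], oracle[[nm]], tolerance = 1e-14,
                   label = sprintf("%s at v=%g cai=%g", nm, v, cai))
    }
    # rows sum to zero (generator property) and no extra transitions
    expect_close(rowSums(Q), rep(0, 10), 1e-12)
    off <- Q; diag(off) <- 0
    expect_equal(sum(off != 0), length(oracle))
  }
})

test_that("cai = 0 disconnects the ladder into five C/O pairs", {
  Q <- bk_rate_matrix(bk_params(), -20, 0)
  off <- Q; diag(off) <- 0
  nz <- which(off != 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - nz[, 2]) == 5))
  expect_error(bk_rate_matrix(bk_params(), -20, -1), "non-negative")
  expect_error(bk_steady_state(bk_params(), -20, 0), "cai")
})

test_that("bk_step matches the Matrix::expm oracle per step", {
  skip_if_not_installed("Matrix")
  par <- bk_params()
  for (case in list(c(-60, 1.5e-4), c(-52, 5e-4), c(-20, 0.002),
                    c(0, 0.01), c(20, 0.05))) {
    v <- case[1]; cai <- case[2]
    # start away from the local steady state
    p0 <- bk_steady_state(par, -80, 1e-4)
    Q <- bk_rate_matrix(par, v, cai)
    got <- bk_step(p0, par, v, cai, dt = 0.04)
    E <- as.matrix(Matrix::expm(Matrix::Matrix(t(Q) * 0.04)))
    oracle <- as.numeric(E %*% p0)
    expect_close(as.numeric(got), oracle, 1e-6)
  }
})

test_that("occupancy is conserved and stays a probability vector", {
  par <- bk_params()
  p <- bk_steady_state(par, -80, 1e-4)
  # drive through a voltage/calcium excursion for 1e5 steps
  vs <- rep(c(-60, -20, 10, -40), each = 25000)
  cas <- rep(c(2e-4, 5e-3, 2e-2, 5e-4), each = 25000)
  worst <- 0
  for (i in seq(1, 1e5, by = 500)) {  # chunked: 200 recorded checks
    for (j in 0:499) {
      k <- i + j
      p <- bk_expm_step(bk_rate_matrix(par, vs[k], cas[k]), p, 0.04)
    }
    worst <- max(worst, abs(sum(p) - 1))
    expect_true(all(p >= 0))
  }
  expect_lt(worst, 1e-9)
})

test_that("steady state is a fixed point and matches long-run simulation", {
  par <- bk_params()
  ss <- bk_steady_state(par, -40, 1e-3)
  stepped <- bk_step(ss, par, -40, 1e-3, dt = 1)
  expect_close(as.numeric(stepped), as.numeric(ss), 1e-9)
  # time-marching oracle from a remote start
  p <- rep(0.1, 10)
  for (i in 1:2000) p <- bk_step(p, par, -40, 1e-3, dt = 5)  # 10^4 ms
  expect_close(as.numeric(p), as.numeric(ss), 1e-6)
})

test_that("canonical form: open probability increases with calcium", {
  par <- bk_params(ca_unbinding = "canonical")
  for (v in c(-60, -40, -20, 0)) {
    po <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1), function(ca) {
      bk_open_probability(par, bk_steady_state(par, v, ca))
    }, numeric(1))
    expect_true(all(diff(po) >= -1e-12),
                label = sprintf("monotone in cai at v = %g", v))
  }
})

test_that("printed form: the documented calcium-direction oddity", {
  # with the published cai factors on the unbinding side, cai cancels from
  # every binding/unbinding ratio and survives only in the closing rate
  # K_O4C4, so steady-state opening *decreases* with calcium
  par <- bk_params(ca_unbinding = "printed")
  po <- vapply(c(1e-4, 1e-3, 1e-2), function(ca) {
    bk_open_probability(par, bk_steady_state(par, -40, ca))
  }, numeric(1))
  expect_true(all(diff(po) < 0))
})

test_that("BK current uses the conducting-state sum and the driving force", {
  par <- bk_params(gmax = 8e-4, e_k = -75)
  # closed states only
  p_closed <- c(rep(0.2, 5), rep(0, 5))
  expect_equal(bk_current(par, p_closed, v = 0), 0)
  # published gmax, O-sum 0.25, driving +60 mV -> 12 uA/cm^2
  p <- c(0.75, 0, 0, 0, 0, 0, 0.1, 0.05, 0.05, 0.05)
  expect_equal(bk_current(par, p, v = -15), 12)
  expect_equal(bk_current(par, p, v = -75), 0)
  # O0 excluded by default; O4-only switch counts only O4
  p0only <- c(0.5, 0, 0, 0, 0, 0.5, 0, 0, 0, 0)
  expect_equal(bk_current(par, p0only, v = 0), 0)
  par4 <- bk_params(conducting = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(bk_current(par4, p, v = -15), 8e-4 * 0.05 * 60 * 1e3)
})
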