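test_that("zero coupling and zero noise give an exactly linear phase", {
  sp1 <- oscillator_spec(2 * pi * 1.1)
  sp2 <- oscillator_spec(2 * pi * 0.25)
  pp <- simulate_phase_pair(sp1, sp2, 60, 50, seed = 1)
  t <- (0:(length(pp$phase1$phi) - 1)) / 50
  expect_close(pp$phase1$phi, 2 * pi * 1.1 * t, 1e-9)
  expect_close(pp$phase2$phi, 2 * pi * 0.25 * t, 1e-9)
})

test_that("noiseless coupled velocity matches the analytic right-hand side", {
  sp1 <- oscillator_spec(2 * pi * 1.1,
                         list(coupling_term(0, 1, "sin", 0.4)))
  sp2 <- oscillator_spec(2 * pi * 0.25)
  fs <- 50
  pp <- simulate_phase_pair(sp1, sp2, 60, fs, seed = 1)
  v <- diff(pp$phase1$phi) * fs
  rhs <- 2 * pi * 1.1 + 0.4 * sin(pp$phase2$phi[-length(pp$phase2$phi)])
  # forward Euler evaluates the RHS at the left endpoint: exact match
  expect_close(v, rhs, 1e-9)
})

test_that("the stepwise and vectorised integrators agree exactly", {
  # a zero-coefficient self-term forces the general loop path
  terms_fast <- list(coupling_term(0, 1, "sin", 0.4))
  terms_loop <- c(terms_fast, list(coupling_term(1, 0, "sin", 0)))
  sp2 <- oscillator_spec(2 * pi * 0.25, noise = 0.2)
  p_fast <- simulate_phase_pair(
    oscillator_spec(2 * pi * 1.1, terms_fast, noise = 0.1), sp2, 60, 25,
    seed = 9)
  p_loop <- simulate_phase_pair(
    oscillator_spec(2 * pi * 1.1, terms_loop, noise = 0.1), sp2, 60, 25,
    seed = 9)
  expect_equal(p_fast$phase1$phi, p_loop$phase1$phi, tolerance = 1e-12)
  expect_equal(p_fast$phase2$phi, p_loop$phase2$phi, tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed and guarded", {
  pp1 <- recovery_pair(seed = 4, duration = 60)
  pp2 <- recovery_pair(seed = 4, duration = 60)
  expect_identical(pp1$phase1$phi, pp2$phase1$phi)
  sp <- oscillator_spec(2 * pi * 1.1)
  expect_error(simulate_phase_pair(sp, sp, 60, fs = 5, seed = 1), "10x")
  expect_error(simulate_phase_pair(sp, sp, 30, fs = 50, seed = 1), "60 s")
})

test_that("coupling produces bounded frequency drift", {
  eps <- 0.4
  pp_c <- recovery_pair(seed = 2, duration = 120, noise = 0, driver_noise = 0)
  sp1 <- oscillator_spec(2 * pi * 1.1); sp2 <- oscillator_spec(2 * pi * 0.25)
  pp_u <- simulate_phase_pair(sp1, sp2, 120, 50, seed = 2)
  T <- 120
  drift <- abs((pp_c$phase1$phi[6000] - pp_c$phase1$phi[1]) -
               (pp_u$phase1$phi[6000] - pp_u$phase1$phi[1])) / T
  expect_lt(drift, eps)
})

test_that("composed observables carry the stated modes", {
  ph_c <- linear_phase(1, 120, 50)
  ph_r <- linear_phase(0.1, 120, 50)
  z <- compose_observable(ph_c, ph_r, amplitudes = c(0, 0), noise_sd = 0)
  expect_true(all(z$samples == 0))
  g <- compose_observable(ph_c, ph_r, amplitudes = c(1, 0), noise_sd = 0)
  expect_close(g$samples[, 1], cos(2 * pi * 1 * (0:5999) / 50), 1e-12)
  ws <- wavelet_transform(g$samples[, 1], 50)
  expect_lt(abs(ridge_frequency(ws) - 1), 1 * (2 ^ (1 / 16) - 1) * 1.01)
  short <- phase_series(ph_r$phi[1:100], 50, kind = "phase")
  expect_error(compose_observable(ph_c, short), "share fs and length")
})

test_that("the default protocol mirrors the four-stage study design", {
  sim <- simulate_protocol(seed = 6)
  expect_equal(record_duration <- nrow(sim$record$samples) / sim$record$fs,
               2400)
  expect_equal(sim$protocol$label, c("A", "B", "C", "D"))
  expect_equal(protocol_spec()$resp_freq_hz[2], 0.1)
  # respiratory 0.1 Hz mode visible during paced stages
  segs <- segment_stages(sim$record, sim$protocol)
  ws <- wavelet_transform(segs$B$samples[, "BP"], sim$record$fs)
  expect_lt(abs(ridge_frequency(ws, band = c(0.07, 0.35)) - 0.1), 0.02)
  # cardiac ridge near 1 Hz throughout
  expect_lt(abs(ridge_frequency(ws, band = c(0.6, 2)) - 1), 0.1)
  sim2 <- simulate_protocol(seed = 6)
  expect_identical(sim$record$samples, sim2$record$samples)
})

test_that("ground-truth terms fold correctly onto the canonical basis", {
  b <- build_basis(2)
  sp <- oscillator_spec(2 * pi, list(coupling_term(0, 1, "sin", 0.4),
                                     coupling_term(0, -1, "sin", 0.1),
                                     coupling_term(-1, 1, "cos", 0.2)))
  cc <- truth_coefficients(sp, b, oscillator = 1)
  expect_equal(cc[1], 2 * pi)
  tb <- b$terms
  # sin(-phi2) = -sin(phi2): folds into sin(0p1+1p2) with flipped sign
  expect_equal(unname(cc[tb$type == "sin" & tb$k1 == 0 & tb$k2 == 1]),
               0.4 - 0.1)
  # cos(-phi1+phi2) = cos(phi1-phi2): folds into cos(1p1-1p2) unchanged
  expect_equal(unname(cc[tb$type == "cos" & tb$k1 == 1 & tb$k2 == -1]), 0.2)
  expect_equal(sum(cc != 0), 3)
})
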