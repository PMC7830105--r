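test_that("moving-average detrend removes slow structure, keeps the passband", {
  fs <- 50
  expect_true(all(moving_average_detrend(rep(3, 1000), fs, 5) == 0))
  t <- (0:5999) / fs
  s <- sin(2 * pi * 1 * t)
  d <- moving_average_detrend(s, fs, 30)
  expect_lt(sqrt(mean((d - s) ^ 2)) / sqrt(mean(s ^ 2)), 0.01)
  ramp <- t
  r <- moving_average_detrend(ramp, fs, 30)
  core <- (30 * fs):(length(ramp) - 30 * fs)
  expect_lt(sqrt(mean(r[core] ^ 2)) / sqrt(mean(ramp[core] ^ 2)), 0.02)
  expect_error(moving_average_detrend(s, fs, 0), "positive")
  expect_error(moving_average_detrend(s, fs, 1000), "shorter")
})

test_that("z-normalisation is exact and idempotent", {
  z <- zscore_normalize(c(1, 2, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)
  expect_close(zscore_normalize(z), z, 1e-12)
  expect_error(zscore_normalize(rep(7, 10)), "constant")
})

test_that("bandpass responses separate cardiac from respiratory content", {
  fs <- 50; t <- (0:11999) / fs
  x <- sin(2 * pi * 1 * t)
  core <- 2000:10000
  card <- bandpass_extract(x, fs, c(0.6, 2), order = 4)
  expect_gt(stats::sd(card$samples[core]) / stats::sd(x[core]), 0.95)
  resp <- bandpass_extract(x, fs, c(0.1, 0.6), order = 4)
  expect_lt(stats::sd(resp$samples[core]) / stats::sd(x[core]), 0.1) # >= 20 dB
  expect_true(all(bandpass_extract(numeric(2000), fs, c(0.6, 2))$samples == 0))
  expect_error(bandpass_extract(x, fs, c(0.6, 30)), "Nyquist")
  # zero-phase: cross-correlation of an in-band tone peaks at lag 0
  cc <- stats::ccf(card$samples[core], x[core], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("protophase of a pure cosine advances linearly at 2 pi f", {
  fs <- 50; f <- 1; T <- 120
  comp <- bandpass_extract(cos(2 * pi * f * (0:(T * fs - 1)) / fs), fs,
                           c(0.6, 2), order = 4)
  pp <- protophase(comp)
  core <- (10 * fs):((T - 10) * fs)
  tt <- (core - 1) / fs
  dev <- pp$phi[core] - 2 * pi * f * tt
  expect_lt(max(abs(dev - mean(dev))), 0.05)
  expect_lt(abs((pp$phi[length(pp$phi)] - pp$phi[1]) - 2 * pi * f * T) /
              (2 * pi * f * T), 0.02)
  expect_error(protophase(numeric(100), fs = 50), "degenerate")
})

test_that("protophase-to-phase restores uniform phase density", {
  # uniform rotation: the transformation is the identity
  proto <- linear_phase(1, 50, 20, kind = "protophase")
  tr <- protophase_to_phase(proto, 48)
  expect_close(tr$phi, proto$phi, 1e-3)
  # known distortion theta = phi + 0.5 sin(phi)
  phi <- seq(0, 2 * pi * 50, length.out = 10001)[-10001]
  theta <- phase_series(phi + 0.5 * sin(phi), fs = 10, kind = "protophase")
  tr <- protophase_to_phase(theta, 48)
  wrapped <- (tr$phi %% (2 * pi)) / (2 * pi)
  ks <- suppressWarnings(stats::ks.test(wrapped, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  # total gain preserved within 2 pi
  gain_in <- theta$phi[10000] - theta$phi[1]
  gain_out <- tr$phi[10000] - tr$phi[1]
  expect_lt(abs(gain_out - gain_in), 2 * pi)
  few <- linear_phase(1, 5, 20, kind = "protophase")
  expect_error(protophase_to_phase(few), "10 cycles")
})

test_that("instantaneous rate converts phase velocity to beats per minute", {
  ph <- phase_series(2 * pi * (0:999) / 50 * 1, fs = 50, kind = "phase")
  r <- instantaneous_rate(ph, smooth_s = 0)
  expect_close(r, 60, 1e-6)
  # RSA-modulated cardiac phase: rate oscillates at the respiratory frequency
  pp <- recovery_pair(seed = 3, duration = 300, noise = 0, driver_noise = 0)
  rate <- instantaneous_rate(pp$phase1, smooth_s = 0.5)
  sp <- stats::spec.pgram(stats::ts(rate - mean(rate), frequency = 50),
                          plot = FALSE, taper = 0)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.25), 0.02)
  expect_error(phase_series(rep(1, 100), 50, kind = "phase"), "advance")
  proto <- linear_phase(1, 60, 50, kind = "protophase")
  expect_error(instantaneous_rate(proto), "kind='phase'")
})

test_that("the full pipeline recovers the true phases within 0.15 rad RMS", {
  sim <- simulate_protocol(seed = 8)
  ph <- extract_phases(sim$record, "BP", run_config())
  fs <- sim$record$fs; trim <- 10 * fs; n <- length(sim$truth$phase_resp$phi)
  for (pair in list(list(ph$cardiac, sim$truth$phases_cardiac$BP),
                    list(ph$respiratory, sim$truth$phase_resp))) {
    err <- pair[[1]]$phi - pair[[2]]$phi[(trim + 1):(n - trim)]
    err <- err - 2 * pi * round(mean(err) / (2 * pi))
    expect_lt(sqrt(mean(err ^ 2)), 0.15)
  }
  expect_equal(ph$cardiac$t0, 10)
})
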