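test_that("the Fourier basis has the canonical size and periodicity", {
  expect_equal(build_basis(1)$n_terms, 9)
  expect_equal(build_basis(2)$n_terms, 25)
  expect_error(build_basis(0), "integer >= 1")
  b <- build_basis(2)
  set.seed(1)
  p1 <- runif(20, 0, 2 * pi); p2 <- runif(20, 0, 2 * pi)
  expect_close(eval_basis(b, p1 + 2 * pi, p2) - eval_basis(b, p1, p2), 0,
               1e-12)
  expect_close(eval_basis(b, p1, p2 - 2 * pi) - eval_basis(b, p1, p2), 0,
               1e-12)
})

test_that("with a flat prior and fixed noise the posterior mean is the
           weighted least-squares solution", {
  b <- build_basis(2)
  sp1 <- oscillator_spec(2 * pi * 1.1,
                         list(coupling_term(0, 1, "sin", 0.3)))
  sp2 <- oscillator_spec(2 * pi * 0.25)
  pp <- simulate_phase_pair(sp1, sp2, 60, 50, seed = 2)
  res <- infer_windows(pp$phase1, pp$phase2, b, window_s = 60,
                       propagation = 0, prior_variance = 1e12,
                       fix_noise = c(0.5, 0.5))
  w <- res$windows[[1]]
  # closed-form oracle: c_i = G^-1 (Phi' v_i - (E_ii/2) dsum_i), built from
  # scratch with plain matrix algebra
  h <- 1 / 50
  for (osc in 1:2) {
    p_self <- if (osc == 1) pp$phase1$phi else pp$phase2$phi
    p1 <- pp$phase1$phi; p2 <- pp$phase2$phi
    v <- diff(p_self) / h
    m1 <- (p1[-1] + p1[-length(p1)]) / 2
    m2 <- (p2[-1] + p2[-length(p2)]) / 2
    tb <- b$terms
    Phi <- sapply(seq_len(b$n_terms), function(j) {
      if (tb$type[j] == "const") return(rep(1, length(m1)))
      a <- tb$k1[j] * m1 + tb$k2[j] * m2
      if (tb$type[j] == "sin") sin(a) else cos(a)
    })
    dsum <- sapply(seq_len(b$n_terms), function(j) {
      if (tb$type[j] == "const") return(0)
      a <- tb$k1[j] * m1 + tb$k2[j] * m2
      kk <- if (osc == 1) tb$k1[j] else tb$k2[j]
      if (tb$type[j] == "sin") sum(kk * cos(a)) else -sum(kk * sin(a))
    })
    oracle <- solve(crossprod(Phi),
                    crossprod(Phi, v) - (0.5 / 2) * dsum)
    expect_close(w$coef[, osc], drop(oracle), 1e-8)
  }
})

test_that("noiseless uncoupled phases are identified exactly", {
  sp1 <- oscillator_spec(2 * pi * 1.1)
  sp2 <- oscillator_spec(2 * pi * 0.25)
  pp <- simulate_phase_pair(sp1, sp2, 60, 50, seed = 1)
  res <- infer_windows(pp$phase1, pp$phase2, build_basis(2), window_s = 60,
                       propagation = 0, prior_variance = 1e12)
  w <- res$windows[[1]]
  expect_lt(abs(w$coef[1, 1] - 2 * pi * 1.1), 1e-6)
  expect_lt(abs(w$coef[1, 2] - 2 * pi * 0.25), 1e-6)
  expect_lt(max(abs(w$coef[-1, ])), 1e-6)
})

test_that("a known sinusoidal coupling is recovered from noisy phases", {
  meds <- sapply(1:3, function(s) {
    pp <- recovery_pair(seed = 40 + s)
    res <- infer_windows(pp$phase1, pp$phase2, build_basis(2), window_s = 50)
    stats::median(sapply(res$windows,
                         function(w) w$coef["sin(+0p1+1p2)", 1]))
  })
  expect_true(all(meds > 0.3 & meds < 0.5))
})

test_that("the inferred noise matches the generating intensity", {
  rel <- sapply(1:5, function(s) {
    pp <- recovery_pair(seed = 60 + s, duration = 300)
    res <- infer_windows(pp$phase1, pp$phase2, build_basis(2), window_s = 50)
    Em <- stats::median(sapply(res$windows, function(w) w$noise[1, 1]))
    sqrt(Em) / 0.1
  })
  expect_lt(abs(stats::median(rel) - 1), 0.2)
})

test_that("posterior variance shrinks as the window grows (noiseless)", {
  sp1 <- oscillator_spec(2 * pi * 1.1,
                         list(coupling_term(0, 1, "sin", 0.3)))
  sp2 <- oscillator_spec(2 * pi * 0.26)
  pp <- simulate_phase_pair(sp1, sp2, 240, 25, seed = 3)
  b <- build_basis(2)
  v <- sapply(c(60, 120, 240), function(ws) {
    r <- infer_windows(pp$phase1, pp$phase2, b, window_s = ws,
                       propagation = 0, fix_noise = c(0.1, 0.1))
    mean(diag(r$windows[[1]]$post_cov))
  })
  expect_true(all(diff(v) < 0))
})

test_that("coupling coefficient extraction selects the partner terms", {
  b <- build_basis(2)
  coef <- matrix(0, b$n_terms, 2,
                 dimnames = list(b$terms$name, c("osc1", "osc2")))
  coef[1, ] <- c(2 * pi, 2 * pi * 0.25)
  est <- structure(list(midtime = 0, coef = coef, noise = diag(2),
                        post_cov = diag(2 * b$n_terms), converged = TRUE),
                   class = "window_estimate")
  expect_true(all(coupling_coefficients(est, 1, b) == 0))
  coef["sin(+0p1+1p2)", 1] <- 1
  est$coef <- coef
  cc <- coupling_coefficients(est, 1, b)
  expect_equal(unname(cc["sin(+0p1+1p2)"]), 1)
  expect_equal(length(cc), sum(b$terms$k2 != 0))
  # sigma is invariant under a rotation of the partner's phase origin:
  # sin(phi2 + a) redistributes over the sin/cos pair, norm unchanged
  a <- 0.9
  coef["sin(+0p1+1p2)", 1] <- cos(a); coef["cos(+0p1+1p2)", 1] <- sin(a)
  est$coef <- coef
  expect_equal(coupling_strength(coupling_coefficients(est, 1, b)), 1)
  expect_error(coupling_coefficients(est, 3, b), "1 or 2")
})

test_that("window inference validates its inputs and flags stages", {
  pp <- recovery_pair(seed = 1, duration = 60)
  backwards <- phase_series(-pp$phase1$phi, 50, kind = "protophase")
  expect_error(infer_windows(backwards, pp$phase2, build_basis(2)),
               "increasing")
  expect_error(infer_windows(pp$phase1, pp$phase2, build_basis(2),
                             window_s = 1), "window too short")
  wt <- window_table(infer_windows(pp$phase1, pp$phase2, build_basis(2),
                                   window_s = 50))
  expect_named(wt, c("midtime", "omega1", "omega2", "strength_in1",
                     "strength_in2", "D", "converged"))
  expect_true(all(wt$converged))
})
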