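#' Phase-oscillator specification
#'
#' Defines one oscillator of a coupled pair by its natural angular frequency,
#' a set of Fourier coupling terms, and the intensity of its dynamical noise.
#' The phase obeys the stochastic model
#' `dphi_i/dt = omega_i + q_i(phi_i, phi_j) + xi_i(t)`,
#' where `q_i` is the sum of the coupling terms and `xi_i` is white Gaussian
#' noise of intensity `noise` (rad/sqrt(s)).
#'
#' @param omega natural frequency in rad/s, > 0.
#' @param coupling list of terms built with [coupling_term()].
#' @param noise dynamical noise intensity in rad/sqrt(s), >= 0.
#' @export
oscillator_spec <- function(omega, coupling = list(), noise = 0) {
  stopifnot(is.numeric(omega), length(omega) == 1L, omega > 0, noise >= 0)
  if (length(coupling) && !all(vapply(coupling, inherits, TRUE,
                                      "coupling_term")))
    stop("coupling must be a list of coupling_term() objects")
  structure(list(omega = omega, coupling = coupling, noise = noise),
            class = "oscillator_spec")
}

#' @rdname oscillator_spec
#' @param k_self,k_other integer multipliers of the oscillator's own phase
#'   and its partner's phase in the term's angle
#'   `k_self * phi_self + k_other * phi_other`.
#' @param fun `"sin"` or `"cos"`.
#' @param coef term coefficient (rad/s).
#' @export
coupling_term <- function(k_self, k_other, fun = c("sin", "cos"), coef) {
  fun <- match.arg(fun)
  stopifnot(k_self == round(k_self), k_other == round(k_other),
            is.numeric(coef), length(coef) == 1L)
  if (k_self == 0 && k_other == 0 && fun == "sin")
    stop("sin(0) term is identically zero")
  structure(list(k_self = as.integer(k_self), k_other = as.integer(k_other),
                 fun = fun, coef = coef), class = "coupling_term")
}

eval_coupling <- function(terms, phi_self, phi_other) {
  q <- 0
  for (tm in terms) {
    ang <- tm$k_self * phi_self + tm$k_other * phi_other
    q <- q + tm$coef * (if (tm$fun == "sin") sin(ang) else cos(ang))
  }
  q
}

depends_on_self <- function(spec) {
  any(vapply(spec$coupling, function(tm) tm$k_self != 0L, TRUE))
}

#' Simulate a coupled phase pair (Euler-Maruyama)
#'
#' Integrates the two-oscillator stochastic phase model at step `1/fs` and
#' returns unwrapped phases plus a ground-truth record of the exact
#' parameters used.
#'
#' When neither coupling function depends on its own oscillator's phase and
#' at most one oscillator is driven (the common respiration-to-cardiac
#' configuration), the integration vectorises exactly; otherwise a stepwise
#' loop is used. Both paths produce the identical Euler-Maruyama recursion.
#'
#' @param spec1,spec2 [oscillator_spec()]s; `spec1`'s coupling terms take
#'   `phi1` as self and `phi2` as partner, and vice versa.
#' @param duration length in seconds (>= 60).
#' @param fs sampling/integration rate in Hz; must be at least 10x the
#'   fastest natural frequency (aliasing guard).
#' @param seed integer RNG seed.
#' @param init initial phases, radians.
#' @return list with `phase1`, `phase2` ([phase_series()], unwrapped) and
#'   `truth` (specs, seed, fs).
#' @export
simulate_phase_pair <- function(spec1, spec2, duration, fs, seed,
                                init = c(0, 0)) {
  stopifnot(inherits(spec1, "oscillator_spec"),
            inherits(spec2, "oscillator_spec"))
  if (duration < 60) stop("duration must be at least 60 s")
  fmax <- max(spec1$omega, spec2$omega) / (2 * pi)
  if (fs < 10 * fmax)
    stop("fs = ", fs, " Hz is below 10x the fastest natural frequency (",
         signif(10 * fmax, 3), " Hz)")
  n <- round(duration * fs)
  h <- 1 / fs
  set.seed(seed)
  xi1 <- if (spec1$noise > 0) stats::rnorm(n - 1, 0, spec1$noise * sqrt(h)) else numeric(n - 1)
  xi2 <- if (spec2$noise > 0) stats::rnorm(n - 1, 0, spec2$noise * sqrt(h)) else numeric(n - 1)

  vectorizable <- !depends_on_self(spec1) && !depends_on_self(spec2) &&
    (length(spec1$coupling) == 0L || length(spec2$coupling) == 0L)
  if (vectorizable) {
    # integrate the undriven oscillator first, then drive the other
    if (length(spec2$coupling) == 0L) {
      phi2 <- c(init[2], init[2] + cumsum(h * spec2$omega + xi2))
      drive <- eval_coupling(spec1$coupling, 0, phi2[-n])
      phi1 <- c(init[1], init[1] + cumsum(h * (spec1$omega + drive) + xi1))
    } else {
      phi1 <- c(init[1], init[1] + cumsum(h * spec1$omega + xi1))
      drive <- eval_coupling(spec2$coupling, 0, phi1[-n])
      phi2 <- c(init[2], init[2] + cumsum(h * (spec2$omega + drive) + xi2))
    }
  } else {
    phi1 <- phi2 <- numeric(n)
    phi1[1] <- init[1]; phi2[1] <- init[2]
    for (m in seq_len(n - 1)) {
      phi1[m + 1] <- phi1[m] + h * (spec1$omega +
        eval_coupling(spec1$coupling, phi1[m], phi2[m])) + xi1[m]
      phi2[m + 1] <- phi2[m] + h * (spec2$omega +
        eval_coupling(spec2$coupling, phi2[m], phi1[m])) + xi2[m]
    }
  }
  list(phase1 = phase_series(phi1, fs, kind = "phase"),
       phase2 = phase_series(phi2, fs, kind = "phase"),
       truth = structure(list(spec1 = spec1, spec2 = spec2, seed = seed,
                              fs = fs), class = "ground_truth"))
}

#' Map an oscillator's coupling terms onto a Fourier basis
#'
#' Expresses the ground-truth coupling terms of `spec` as a coefficient
#' vector aligned to [build_basis()], for direct comparison with inferred
#' coefficients. `oscillator` states whether the spec describes oscillator 1
#' (self phase = phi1) or 2 (self phase = phi2).
#'
#' @param spec an [oscillator_spec()].
#' @param basis a [build_basis()] object.
#' @param oscillator 1 or 2.
#' @return numeric coefficient vector of length `basis$n_terms` (constant
#'   term carries `omega`).
#' @export
truth_coefficients <- function(spec, basis, oscillator = 1) {
  cc <- numeric(basis$n_terms)
  cc[1] <- spec$omega
  tab <- basis$terms
  for (tm in spec$coupling) {
    if (oscillator == 1) { k1 <- tm$k_self; k2 <- tm$k_other }
    else                 { k1 <- tm$k_other; k2 <- tm$k_self }
    fun <- tm$fun; coef <- tm$coef
    if (max(abs(k1), abs(k2)) > basis$K)
      stop("coupling term outside basis order K = ", basis$K)
    # fold onto the canonical half-plane: sin is odd, cos even in the angle
    if (k1 < 0 || (k1 == 0 && k2 < 0)) {
      k1 <- -k1; k2 <- -k2
      if (fun == "sin") coef <- -coef
    }
    hit <- which(tab$type == fun & tab$k1 == k1 & tab$k2 == k2)
    stopifnot(length(hit) == 1L)
    cc[hit] <- cc[hit] + coef
  }
  cc
}

#' Compose an observable signal from cardiac and respiratory phases
#'
#' Builds `g(t) = A_c cos(phi_c) + A_r cos(phi_r) + eps(t)` with white
#' Gaussian measurement noise, the simplest observable carrying both
#' oscillatory modes.
#'
#' @param phase_cardiac,phase_resp [phase_series()] of equal `fs` and length.
#' @param amplitudes numeric length 2: `c(cardiac, respiratory)` amplitudes.
#'   May be vectors of the series length for stage-varying amplitudes.
#' @param noise_sd measurement noise standard deviation (may be a vector).
#' @param seed integer RNG seed.
#' @param channel channel name of the single-channel output record.
#' @return a one-channel [signal_record()].
#' @export
compose_observable <- function(phase_cardiac, phase_resp,
                               amplitudes = c(1, 0.5), noise_sd = 0,
                               seed = 1, channel = "X") {
  stopifnot(inherits(phase_cardiac, "phase_series"),
            inherits(phase_resp, "phase_series"))
  if (length(phase_cardiac$phi) != length(phase_resp$phi) ||
      phase_cardiac$fs != phase_resp$fs)
    stop("cardiac and respiratory phases must share fs and length")
  n <- length(phase_cardiac$phi)
  a_c <- rep_len(if (is.list(amplitudes)) amplitudes[[1]] else amplitudes[[1]], n)
  a_r <- rep_len(if (is.list(amplitudes)) amplitudes[[2]] else amplitudes[[2]], n)
  set.seed(seed)
  eps <- if (any(noise_sd > 0)) stats::rnorm(n, 0, rep_len(noise_sd, n)) else numeric(n)
  g <- a_c * cos(phase_cardiac$phi) + a_r * cos(phase_resp$phi) + eps
  m <- matrix(g, ncol = 1, dimnames = list(NULL, channel))
  signal_record(m, fs = phase_cardiac$fs, t0 = phase_cardiac$t0)
}

#' Four-stage slow-breathing protocol specification
#'
#' Per-stage generator parameters emulating the study protocol: (A) baseline
#' free breathing, (B) paced 6 breaths/min, (C) paced 6 breaths/min with
#' inspiratory resistance, (D) recovery, 10 minutes each. Stages B and C set
#' the respiratory frequency to 0.1 Hz, multiply the respiration-to-cardiac
#' coupling gain (x2 and x3), raise the respiratory observation amplitude,
#' and shift the coupling-function phase along the respiratory axis (the
#' paced-breathing form change; restored in D).
#'
#' @param label stage labels.
#' @param duration_s stage durations, seconds.
#' @param resp_freq_hz paced/spontaneous respiratory frequency per stage.
#' @param gain_mult respiration-to-cardiac coupling gain multiplier per stage.
#' @param coupling_shift phase shift (rad) of the coupling function along the
#'   respiratory phase axis per stage.
#' @param amp_resp,amp_cardiac observation amplitudes per stage.
#' @param noise_sd measurement noise sd per stage.
#' @param resp_noise respiratory dynamical noise intensity per stage,
#'   rad/sqrt(s). Defaults emulate realistic breathing-cycle variability:
#'   spontaneous breathing (A, D) has cycle-duration CV around 15%
#'   (0.3 rad/sqrt(s) at 0.25 Hz), paced breathing (B, C) is much more
#'   regular (0.08).
#' @return a `protocol_spec` data frame.
#' @export
protocol_spec <- function(label = c("A", "B", "C", "D"),
                          duration_s = rep(600, 4),
                          resp_freq_hz = c(0.25, 0.1, 0.1, 0.25),
                          gain_mult = c(1, 2, 3, 1),
                          coupling_shift = c(0, 1.2, 1.2, 0),
                          amp_resp = c(0.5, 1.0, 1.3, 0.5),
                          amp_cardiac = rep(1, 4),
                          noise_sd = rep(0.1, 4),
                          resp_noise = c(0.3, 0.08, 0.08, 0.3)) {
  stopifnot(all(duration_s > 0), all(resp_freq_hz > 0), all(resp_noise >= 0))
  structure(data.frame(label = label, duration_s = duration_s,
                       resp_freq_hz = resp_freq_hz, gain_mult = gain_mult,
                       coupling_shift = coupling_shift, amp_resp = amp_resp,
                       amp_cardiac = amp_cardiac, noise_sd = noise_sd,
                       resp_noise = resp_noise,
                       stringsAsFactors = FALSE),
            class = c("protocol_spec", "data.frame"))
}

#' Simulate a full multichannel protocol recording
#'
#' Generates one subject: a shared respiratory phase plus one cardiac phase
#' per channel, each cardiac phase driven by the respiratory phase through a
#' stage-dependent sinusoidal coupling (the respiratory sinus arrhythmia
#' mechanism), then composes BP-like and SAS-like observables per channel.
#' Phases are continuous across stage boundaries; generator parameters
#' switch stepwise at the boundaries.
#'
#' @param protocol a [protocol_spec()].
#' @param fs sampling rate in Hz (default 50).
#' @param seed integer RNG seed.
#' @param channels channel names; one cardiac oscillator each.
#' @param base_gain respiration-to-cardiac coupling gain (rad/s) at stage
#'   multiplier 1.
#' @param cardiac_freq_hz per-channel cardiac natural frequencies (recycled).
#' @param cardiac_noise cardiac dynamical noise intensity, rad/sqrt(s);
#'   the respiratory noise is stage-dependent and lives in the protocol.
#' @return list with `record` (a [signal_record()]), `protocol` (a
#'   [stage_protocol()]), and `truth` (per-stage true parameters and phases).
#' @export
simulate_protocol <- function(protocol = protocol_spec(), fs = 50, seed = 1,
                              channels = c("BP", "SAS_LEFT", "SAS_RIGHT"),
                              base_gain = 0.2,
                              cardiac_freq_hz = c(1.0, 1.03, 0.97),
                              cardiac_noise = 0.1) {
  stopifnot(inherits(protocol, "protocol_spec"), nrow(protocol) >= 1)
  n_st <- nrow(protocol)
  starts <- cumsum(c(0, protocol$duration_s))[seq_len(n_st)]
  ends <- starts + protocol$duration_s
  n_per <- round(protocol$duration_s * fs)
  n <- sum(n_per)
  h <- 1 / fs
  stage_of <- rep.int(seq_len(n_st), n_per)   # stage of each sample

  f_card <- rep_len(cardiac_freq_hz, length(channels))
  if (fs < 10 * max(f_card)) stop("fs below 10x the cardiac frequency")

  set.seed(seed)
  # respiratory phase: stepwise frequency, no incoming coupling -> vectorised
  omega_r <- 2 * pi * protocol$resp_freq_hz[stage_of]
  sd_r <- protocol$resp_noise[stage_of] * sqrt(h)
  dphi_r <- h * omega_r[-n] +
    (if (any(sd_r > 0)) stats::rnorm(n - 1, 0, sd_r[-n]) else 0)
  phi_r <- c(0, cumsum(dphi_r))

  gain <- base_gain * protocol$gain_mult[stage_of]
  shift <- protocol$coupling_shift[stage_of]
  phases_c <- list()
  for (ch in seq_along(channels)) {
    drive <- gain[-n] * sin(phi_r[-n] + shift[-n])
    dphi_c <- h * (2 * pi * f_card[ch] + drive) +
      (if (cardiac_noise > 0) stats::rnorm(n - 1, 0, cardiac_noise * sqrt(h)) else 0)
    phi0 <- stats::runif(1, 0, 2 * pi)
    phases_c[[channels[ch]]] <- phase_series(c(phi0, phi0 + cumsum(dphi_c)),
                                             fs, kind = "phase")
  }
  phase_r <- phase_series(phi_r, fs, kind = "phase")

  a_r <- protocol$amp_resp[stage_of]
  a_c <- protocol$amp_cardiac[stage_of]
  sd_m <- protocol$noise_sd[stage_of]
  samples <- matrix(NA_real_, n, length(channels),
                    dimnames = list(NULL, channels))
  for (ch in channels) {
    eps <- stats::rnorm(n, 0, sd_m)
    samples[, ch] <- a_c * cos(phases_c[[ch]]$phi) + a_r * cos(phi_r) + eps
  }

  truth <- structure(list(
    phase_resp = phase_r, phases_cardiac = phases_c,
    stage_gain = base_gain * protocol$gain_mult,
    stage_shift = protocol$coupling_shift,
    stage_resp_freq = protocol$resp_freq_hz,
    cardiac_freq_hz = f_card, base_gain = base_gain,
    stage_resp_noise = protocol$resp_noise, cardiac_noise = cardiac_noise,
    seed = seed), class = "ground_truth")

  list(record = signal_record(samples, fs = fs),
       protocol = stage_protocol(protocol$label, starts, ends),
       truth = truth)
}
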