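#' Phase series
#'
#' Unwrapped instantaneous phase of one oscillatory mode.
#'
#' @param phi numeric vector of unwrapped phase, radians.
#' @param fs sampling rate in Hz.
#' @param kind `"protophase"` (raw analytic-signal angle, observable
#'   dependent) or `"phase"` (invariant phase with uniform density).
#' @param t0 time of the first sample, seconds.
#' @export
phase_series <- function(phi, fs, kind = c("phase", "protophase"), t0 = 0) {
  kind <- match.arg(kind)
  if (any(!is.finite(phi))) stop("phase contains non-finite values")
  if (kind == "phase" && length(phi) > 1 &&
      (phi[length(phi)] - phi[1]) <= 0)
    stop("phase must advance: mean velocity must be positive")
  structure(list(phi = phi, fs = fs, kind = kind, t0 = t0),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series:%s> %d samples at %g Hz, %.1f cycles\n",
              x$kind, length(x$phi), x$fs,
              (x$phi[length(x$phi)] - x$phi[1]) / (2 * pi)))
  invisible(x)
}

n_cycles <- function(phase) (phase$phi[length(phase$phi)] - phase$phi[1]) / (2 * pi)

#' Moving-average detrend
#'
#' Subtracts a centered moving average of width `window_s`; at the record
#' edges the window shrinks symmetrically-as-possible rather than padding.
#'
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @param window_s window width, seconds; must be positive and shorter than
#'   the record.
#' @return detrended samples.
#' @export
moving_average_detrend <- function(x, fs, window_s) {
  if (window_s <= 0) stop("window_s must be positive")
  n <- length(x)
  if (window_s >= n / fs) stop("window_s must be shorter than the record")
  half <- floor(round(window_s * fs) / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  x - (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Z-score normalisation
#'
#' Subtracts the mean and divides by the standard deviation.
#'
#' @param x numeric samples with positive standard deviation.
#' @export
zscore_normalize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("constant (or degenerate) input cannot be z-normalised")
  (x - mean(x)) / s
}

#' Zero-phase Butterworth bandpass
#'
#' Extracts one oscillatory mode with a Butterworth bandpass applied
#' forward-backward (`signal::filtfilt`), i.e. zero phase distortion and
#' doubled effective order.
#'
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @param band length-2 numeric, band edges in Hz, inside `(0, fs/2)`.
#' @param order Butterworth order per pass (default 2).
#' @param label band label, e.g. `"respiratory"` or `"cardiac"`.
#' @return a `band_component`: list with `samples`, `band`, `fs`, `label`.
#' @export
bandpass_extract <- function(x, fs, band, order = 2, label = "band") {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band edge at or above the Nyquist frequency: band must lie ",
         "strictly inside (0, fs/2)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  structure(list(samples = y, band = band, fs = fs, label = label),
            class = "band_component")
}

# Analytic signal via the FFT: zero negative frequencies, double positive.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

unwrap_phase <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

#' Protophase from the analytic signal
#'
#' Angle of the analytic signal of a narrowband component, unwrapped. The
#' protophase depends on the observable; use [protophase_to_phase()] to map
#' it to the invariant phase.
#'
#' @param component a `band_component` from [bandpass_extract()], or a
#'   numeric vector with `fs` supplied.
#' @param fs sampling rate (only if `component` is a bare numeric vector).
#' @return a [phase_series()] of kind `"protophase"`.
#' @export
protophase <- function(component, fs = NULL) {
  if (inherits(component, "band_component")) {
    x <- component$samples; fs <- component$fs
  } else {
    x <- component
    if (is.null(fs)) stop("fs required for bare numeric input")
  }
  if (all(x == 0) || stats::sd(x) == 0)
    stop("degenerate (constant/zero) component has no phase")
  a <- analytic_signal(x)
  phase_series(unwrap_phase(Arg(a)), fs, kind = "protophase")
}

#' Protophase-to-phase transformation
#'
#' Maps an observable-dependent protophase theta to the invariant phase with
#' uniform wrapped density, via the empirical Fourier coefficients
#' `S_n = <exp(-i n theta)>` of the wrapped protophase distribution:
#' `phi(theta) = theta + sum_{0<|n|<=N} S_n/(i n) (exp(i n theta) - 1)`.
#' The map satisfies `phi(theta + 2 pi) = phi(theta) + 2 pi`, so cycle count
#' and total phase gain are preserved.
#'
#' @param proto a [phase_series()] of kind `"protophase"` covering at least
#'   10 cycles.
#' @param n_harmonics number of harmonics N (default 48).
#' @return a [phase_series()] of kind `"phase"`.
#' @export
protophase_to_phase <- function(proto, n_harmonics = 48) {
  stopifnot(inherits(proto, "phase_series"))
  if (proto$kind != "protophase")
    warning("input already of kind 'phase'; transforming anyway")
  if (n_cycles(proto) < 10)
    stop("protophase must cover at least 10 cycles (has ",
         round(n_cycles(proto), 1), ")")
  th <- proto$phi
  z <- exp(1i * th)            # exp(i n theta) built by cumulative products
  phi <- th
  zn <- rep(1 + 0i, length(th))
  for (n in seq_len(n_harmonics)) {
    zn <- zn * z
    S_n <- mean(Conj(zn))
    phi <- phi + 2 * Re((S_n / (1i * n)) * (zn - 1))
  }
  phase_series(phi, proto$fs, kind = "phase", t0 = proto$t0)
}

#' Instantaneous rate from a phase series
#'
#' `60 * dphi/dt / (2 pi)` in beats (or cycles) per minute, with the phase
#' velocity from centered finite differences and a centered moving-average
#' smoother.
#'
#' @param phase a [phase_series()] of kind `"phase"`.
#' @param smooth_s smoothing window, seconds (0 = none).
#' @return numeric vector of rates, beats/min, same length as the phase.
#' @export
instantaneous_rate <- function(phase, smooth_s = 0.25) {
  stopifnot(inherits(phase, "phase_series"))
  if (phase$kind != "phase") stop("instantaneous_rate requires kind='phase'")
  phi <- phase$phi; fs <- phase$fs; n <- length(phi)
  if (n < 3) stop("phase too short")
  v <- numeric(n)
  v[2:(n - 1)] <- (phi[3:n] - phi[1:(n - 2)]) * fs / 2
  v[1] <- (phi[2] - phi[1]) * fs
  v[n] <- (phi[n] - phi[n - 1]) * fs
  if (any(!is.finite(v))) stop("non-finite phase velocity")
  if (smooth_s > 0 && round(smooth_s * fs) >= 2) {
    half <- floor(round(smooth_s * fs) / 2)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
    v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  60 * v / (2 * pi)
}

#' Extract respiratory and cardiac phases from one channel
#'
#' The full conditioning pipeline: moving-average detrend, z-normalisation,
#' zero-phase Butterworth bandpass into the respiratory and cardiac bands,
#' analytic-signal protophase, and protophase-to-phase transformation.
#' The first and last `edge_trim_s` seconds are discarded (filter and
#' analytic-signal edge effects).
#'
#' @param record a [signal_record()].
#' @param channel channel name.
#' @param config a [run_config()].
#' @return list with elements `respiratory` and `cardiac`, each a
#'   [phase_series()] of kind `"phase"` whose `t0` reflects the trim.
#' @export
extract_phases <- function(record, channel, config = run_config()) {
  stopifnot(inherits(record, "signal_record"),
            channel %in% colnames(record$samples))
  x <- record$samples[, channel]
  fs <- record$fs
  x <- moving_average_detrend(x, fs, config$detrend_window_s)
  x <- zscore_normalize(x)
  out <- list()
  bands <- list(respiratory = config$resp_band, cardiac = config$cardiac_band)
  trim <- round(config$edge_trim_s * fs)
  for (lab in names(bands)) {
    comp <- bandpass_extract(x, fs, bands[[lab]], config$filter_order, lab)
    ph <- protophase_to_phase(protophase(comp), config$proto_harmonics)
    keep <- seq.int(trim + 1L, length(ph$phi) - trim)
    out[[lab]] <- phase_series(ph$phi[keep], fs, kind = "phase",
                               t0 = record$t0 + trim / fs)
  }
  out
}
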