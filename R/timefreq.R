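#' Morlet wavelet configuration
#'
#' Logarithmic frequency grid for the continuous wavelet transform. The
#' default interval 0.07-2 Hz spans the respiratory and cardiac activity of
#' interest.
#'
#' @param fmin,fmax frequency interval, Hz.
#' @param voices voices per octave (grid density).
#' @export
wavelet_config <- function(fmin = 0.07, fmax = 2, voices = 16) {
  stopifnot(fmin > 0, fmax > fmin, voices >= 1)
  structure(list(fmin = fmin, fmax = fmax, voices = voices),
            class = "wavelet_config")
}

#' Morlet continuous wavelet transform
#'
#' Computes `W(s, t) = (1/s) * integral phi((u - t)/s) g(u) du` with the
#' Morlet mother wavelet
#' `phi(u) = pi^(-1/4) exp(-i 2 pi u) exp(-u^2 / 2)` and the frequency-scale
#' map `f = 1/s` (central frequency 1). Note the `1/s` normalisation (not
#' the more common `1/sqrt(s)`): ridge amplitude is then proportional to
#' component amplitude across frequencies. Computed exactly in the frequency
#' domain: at scale `s` the transform multiplies the signal spectrum by
#' `sqrt(2 pi) pi^(-1/4) exp(-2 pi^2 (s f - 1)^2)`, a Gaussian around
#' `f = 1/s` (negative frequencies are negligibly weighted, so the result is
#' analytic and the ridge phase advances at `+2 pi f`).
#'
#' @param x numeric samples.
#' @param fs sampling rate, Hz.
#' @param config a [wavelet_config()]; `fmax` must not exceed `fs/2` and the
#'   record must cover at least 3 periods of `fmin`.
#' @return a `wavelet_spectrum`: list with `frequencies` (Hz, ascending),
#'   `times` (s), complex coefficient matrix `coef` (frequencies x times),
#'   and a logical cone-of-influence matrix `coi` (TRUE = inside the
#'   reliable cone, `|t - edge| >= s * sqrt(2)`).
#' @export
wavelet_transform <- function(x, fs, config = wavelet_config()) {
  stopifnot(inherits(config, "wavelet_config"))
  n <- length(x)
  if (config$fmax > fs / 2) stop("fmax exceeds the Nyquist frequency")
  if (n / fs < 3 / config$fmin)
    stop("record shorter than 3 periods of fmin")
  n_oct <- log2(config$fmax / config$fmin)
  freqs <- config$fmin * 2 ^ (seq(0, n_oct, by = 1 / config$voices))
  # pad to reduce circular wrap-around of the slowest wavelets
  npad <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(npad - n)))
  fgrid <- c(seq(0, floor(npad / 2)), seq(-ceiling(npad / 2) + 1, -1)) *
    fs / npad
  coef <- matrix(0i, length(freqs), n)
  tvec <- (seq_len(n) - 1) / fs
  norm <- sqrt(2 * pi) * pi ^ (-1 / 4)
  for (k in seq_along(freqs)) {
    s <- 1 / freqs[k]
    win <- norm * exp(-2 * pi ^ 2 * (s * fgrid - 1) ^ 2)
    coef[k, ] <- (stats::fft(X * win, inverse = TRUE) / npad)[seq_len(n)]
  }
  coi <- outer(1 / freqs * sqrt(2), tvec,
               function(s, t) t >= s & t <= (n - 1) / fs - s)
  structure(list(frequencies = freqs, times = tvec, coef = coef, coi = coi),
            class = "wavelet_spectrum")
}

#' Amplitude and phase surfaces of a wavelet spectrum
#'
#' Splits the complex coefficients `X = a + i b` into the amplitude
#' `sqrt(a^2 + b^2)` and the quadrant-aware phase `atan2(b, a)` in
#' `(-pi, pi]`.
#'
#' @param spectrum a `wavelet_spectrum` from [wavelet_transform()].
#' @return list with matrices `amplitude` and `phase`.
#' @export
amplitude_phase <- function(spectrum) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  list(amplitude = Mod(spectrum$coef), phase = Arg(spectrum$coef))
}

#' Ridge frequency of a wavelet spectrum
#'
#' For each time step (or averaged over time), the grid frequency of maximal
#' amplitude. Convenience accessor used to confirm the cardiac (~1 Hz) and
#' respiratory (0.1-0.35 Hz) modes.
#'
#' @param spectrum a `wavelet_spectrum`.
#' @param band optional frequency band (Hz) to restrict the search.
#' @param average if TRUE (default) return the single frequency maximising
#'   the time-averaged amplitude; otherwise per-time ridge frequencies.
#' @export
ridge_frequency <- function(spectrum, band = NULL, average = TRUE) {
  amp <- Mod(spectrum$coef)
  sel <- rep(TRUE, length(spectrum$frequencies))
  if (!is.null(band))
    sel <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  f <- spectrum$frequencies[sel]
  a <- amp[sel, , drop = FALSE]
  if (average) f[which.max(rowMeans(a))] else f[apply(a, 2, which.max)]
}
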