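#' Fourier basis for the coupled phase-oscillator model
#'
#' The phase dynamics of each oscillator is expanded as
#' `dphi_i/dt = sum_k c_k^(i) Phi_k(phi1, phi2)`, where the `Phi_k` are a
#' constant term plus `sin(k1 phi1 + k2 phi2)` and `cos(k1 phi1 + k2 phi2)`
#' for all integer pairs `(k1, k2) != (0, 0)` with `|k1|, |k2| <= K`,
#' enumerated over the canonical half-plane `k1 > 0, or k1 = 0 and k2 > 0`
#' (the other half is redundant by parity). Term count is `(2K+1)^2`.
#'
#' @param K order of the Fourier expansion (the study uses K = 2).
#' @return a `fourier_basis`: list with `K`, `n_terms`, and a data frame
#'   `terms` (columns `type` in const/sin/cos, `k1`, `k2`) in canonical
#'   order.
#' @export
build_basis <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("K must be an integer >= 1")
  K <- as.integer(K)
  pairs <- expand.grid(k2 = -K:K, k1 = 0:K)[, c("k1", "k2")]
  pairs <- pairs[pairs$k1 > 0 | (pairs$k1 == 0 & pairs$k2 > 0), ]
  pairs <- pairs[order(pairs$k1, pairs$k2), ]
  terms <- rbind(
    data.frame(type = "const", k1 = 0L, k2 = 0L),
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      data.frame(type = c("sin", "cos"), k1 = pairs$k1[i], k2 = pairs$k2[i]))))
  rownames(terms) <- NULL
  terms$name <- ifelse(terms$type == "const", "const",
                       sprintf("%s(%+dp1%+dp2)", terms$type, terms$k1,
                               terms$k2))
  structure(list(K = K, n_terms = nrow(terms), terms = terms),
            class = "fourier_basis")
}

#' Evaluate the basis at phase pairs
#'
#' @param basis a [build_basis()] object.
#' @param phi1,phi2 numeric phase vectors of equal length.
#' @return numeric matrix, rows = observations, columns = basis terms in
#'   canonical order.
#' @export
eval_basis <- function(basis, phi1, phi2) {
  stopifnot(inherits(basis, "fourier_basis"), length(phi1) == length(phi2))
  tb <- basis$terms
  out <- matrix(NA_real_, length(phi1), basis$n_terms,
                dimnames = list(NULL, tb$name))
  out[, 1] <- 1
  for (j in 2:basis$n_terms) {
    ang <- tb$k1[j] * phi1 + tb$k2[j] * phi2
    out[, j] <- if (tb$type[j] == "sin") sin(ang) else cos(ang)
  }
  out
}

# Column sums of d Phi_k / d phi_i over the observations, i in {1, 2}.
# d sin(a)/d phi_i = k_i cos(a); d cos(a)/d phi_i = -k_i sin(a).
basis_deriv_colsums <- function(basis, Phi, wrt) {
  tb <- basis$terms
  k <- if (wrt == 1) tb$k1 else tb$k2
  out <- numeric(basis$n_terms)
  for (j in 2:basis$n_terms) {
    if (k[j] == 0) next
    partner <- j + if (tb$type[j] == "sin") 1L else -1L  # its sin/cos twin
    out[j] <- if (tb$type[j] == "sin") k[j] * sum(Phi[, partner])
              else                    -k[j] * sum(Phi[, partner])
  }
  out
}

#' Windowed dynamical Bayesian inference of a coupled phase pair
#'
#' Splits the two phase series into consecutive non-overlapping windows and,
#' per window, infers the Fourier coefficients `c` of both oscillators'
#' phase dynamics and the 2x2 dynamical noise matrix `E`, propagating the
#' posterior of each window (with diagonal diffusion) as the next window's
#' prior.
#'
#' Within a window of `N + 1` samples at step `h = 1/fs`, with phase
#' velocities `v_n = (phi_{n+1} - phi_n)/h` and the basis evaluated at the
#' midpoints `(phi_{n+1} + phi_n)/2`, the scheme alternates until
#' convergence:
#' \itemize{
#'   \item noise update: `E = (h/N) sum_n r_n r_n'` with residuals
#'     `r_n = v_n - C' Phi_n` (columns of `C` are the two coefficient
#'     vectors);
#'   \item coefficient update: with the stacked vector `c = (c1, c2)`,
#'     precision `Xi = Xi_prior + h * kron(E^-1, sum_n Phi_n Phi_n')` and
#'     `r = Xi_prior c_prior + h * [sum_j (E^-1)_{ij} sum_n Phi_n v_{j,n}]_i`
#'     `- (h/2) * [sum_n dPhi_n/dphi_i]_i`, then `c = Xi^-1 r`.
#' }
#' The final `-(h/2) sum dPhi/dphi_i` term is the Ito drift correction of the
#' midpoint discretisation. Between windows the prior mean is the previous
#' posterior mean and the prior covariance is the posterior covariance
#' inflated diagonally by `(propagation * c_post)^2` per coefficient; with
#' `propagation = 0` each window restarts from the initial weak prior
#' (independent windows).
#'
#' @param phase1,phase2 [phase_series()] of equal `fs` and length with
#'   positive mean velocity (convention: 1 = cardiac, 2 = respiratory).
#' @param basis a [build_basis()] object (default K = 2).
#' @param window_s window length in seconds; `window_s * fs` must be at
#'   least 4x the basis size.
#' @param propagation prior-diffusion constant (default 0.2).
#' @param prior_variance initial prior variance per coefficient.
#' @param tol relative change of `||c||` declaring convergence.
#' @param max_iter iteration cap; windows hitting it are flagged
#'   (`converged = FALSE`), never silently dropped.
#' @param fix_noise optional fixed 2x2 noise matrix (or length-2 diagonal);
#'   skips the noise update (used for oracle checks).
#' @return an `inference_result`: list of per-window estimates (`midtime`,
#'   coefficient matrix `coef` of size n_terms x 2, `noise`, posterior
#'   covariance `post_cov`, `converged`) plus the basis and settings.
#' @export
infer_windows <- function(phase1, phase2, basis = build_basis(2),
                          window_s = 50, propagation = 0.2,
                          prior_variance = 100, tol = 1e-5, max_iter = 100,
                          fix_noise = NULL) {
  stopifnot(inherits(phase1, "phase_series"), inherits(phase2, "phase_series"),
            inherits(basis, "fourier_basis"))
  if (phase1$fs != phase2$fs || length(phase1$phi) != length(phase2$phi))
    stop("phase series must share fs and length")
  fs <- phase1$fs; h <- 1 / fs
  for (p in list(phase1, phase2))
    if ((p$phi[length(p$phi)] - p$phi[1]) <= 0)
      stop("phase must be increasing on average")
  wlen <- round(window_s * fs)
  B <- basis$n_terms
  if (wlen < 4 * B)
    stop("window too short: need window_s * fs >= 4 * basis size (",
         4 * B, ")")
  n <- length(phase1$phi)
  n_win <- floor(n / wlen)
  if (n_win < 1) stop("record shorter than one window")

  if (!is.null(fix_noise)) {
    fix_noise <- if (length(fix_noise) == 2L) diag(fix_noise, 2)
                 else as.matrix(fix_noise)
    stopifnot(all(dim(fix_noise) == 2L))
  }

  prior_mean0 <- numeric(2 * B)
  prior_prec0 <- diag(1 / prior_variance, 2 * B)
  prior_mean <- prior_mean0
  prior_prec <- prior_prec0

  windows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    p1 <- phase1$phi[idx]; p2 <- phase2$phi[idx]
    v1 <- diff(p1) / h; v2 <- diff(p2) / h
    m1 <- (p1[-1] + p1[-length(p1)]) / 2
    m2 <- (p2[-1] + p2[-length(p2)]) / 2
    Phi <- eval_basis(basis, m1, m2)
    N <- nrow(Phi)
    G <- crossprod(Phi)
    Pv1 <- crossprod(Phi, v1); Pv2 <- crossprod(Phi, v2)
    drift <- (h / 2) * c(basis_deriv_colsums(basis, Phi, 1),
                         basis_deriv_colsums(basis, Phi, 2))

    cvec <- prior_mean
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      C <- matrix(cvec, B, 2)
      if (is.null(fix_noise)) {
        R <- cbind(v1, v2) - Phi %*% C
        E <- (h / N) * crossprod(R)
        # guard against numerically singular noise on noiseless input
        E <- E + diag(1e-12, 2)
      } else E <- fix_noise
      invE <- solve(E)
      Xi <- prior_prec + h * (invE %x% G)
      r <- drop(prior_prec %*% prior_mean) +
        h * c(invE[1, 1] * Pv1 + invE[1, 2] * Pv2,
              invE[2, 1] * Pv1 + invE[2, 2] * Pv2) - drift
      cnew <- drop(solve(Xi, r))
      delta <- sqrt(sum((cnew - cvec) ^ 2)) / max(sqrt(sum(cnew ^ 2)), 1e-12)
      cvec <- cnew
      if (!is.null(fix_noise) && it >= 1) { converged <- TRUE; break }
      if (delta < tol) { converged <- TRUE; break }
    }
    post_cov <- solve(Xi)
    windows[[w]] <- structure(list(
      midtime = phase1$t0 + (idx[1] + idx[length(idx)] - 2) / 2 * h,
      coef = matrix(cvec, B, 2,
                    dimnames = list(basis$terms$name, c("osc1", "osc2"))),
      noise = E, post_cov = post_cov, converged = converged),
      class = "window_estimate")

    if (propagation > 0) {
      S <- post_cov + diag((propagation * cvec) ^ 2, 2 * B)
      prior_prec <- solve(S)
      prior_mean <- cvec
    } else {
      prior_prec <- prior_prec0
      prior_mean <- prior_mean0
    }
  }
  structure(list(windows = windows, basis = basis, fs = fs,
                 window_s = window_s, propagation = propagation,
                 prior_variance = prior_variance),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> %d windows of %g s, basis K = %d (%d terms)\n",
              length(x$windows), x$window_s, x$basis$K, x$basis$n_terms))
  invisible(x)
}

#' Coupling coefficients acting on one oscillator
#'
#' Extracts, from a window estimate, the coefficients of the basis terms
#' through which the partner oscillator influences oscillator `i`: the terms
#' of oscillator `i`'s equation whose index in the partner's phase is
#' nonzero.
#'
#' @param estimate a `window_estimate` from [infer_windows()].
#' @param i target oscillator, 1 or 2.
#' @param basis the basis the estimate was made with.
#' @return named numeric coefficient subvector (canonical order).
#' @export
coupling_coefficients <- function(estimate, i, basis) {
  stopifnot(inherits(estimate, "window_estimate"),
            inherits(basis, "fourier_basis"))
  if (!i %in% c(1, 2)) stop("oscillator index must be 1 or 2")
  kpartner <- if (i == 1) basis$terms$k2 else basis$terms$k1
  sel <- kpartner != 0
  estimate$coef[sel, i]
}

#' Per-window measure table
#'
#' Flattens an inference result into a data frame with, per window, the
#' midtime, both natural frequencies, the directed coupling strengths
#' (norm of coupling coefficients into each oscillator), and the
#' directionality index.
#'
#' @param result an `inference_result`.
#' @return data frame with columns `midtime`, `omega1`, `omega2`,
#'   `strength_in1`, `strength_in2`, `D`, `converged`.
#' @export
window_table <- function(result) {
  stopifnot(inherits(result, "inference_result"))
  basis <- result$basis
  rows <- lapply(result$windows, function(w) {
    c1 <- coupling_strength(coupling_coefficients(w, 1, basis))
    c2 <- coupling_strength(coupling_coefficients(w, 2, basis))
    data.frame(midtime = w$midtime, omega1 = w$coef[1, 1],
               omega2 = w$coef[1, 2], strength_in1 = c1, strength_in2 = c2,
               D = if (c1 + c2 > 0) (c2 - c1) / (c1 + c2) else NA_real_,
               converged = w$converged)
  })
  do.call(rbind, rows)
}
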