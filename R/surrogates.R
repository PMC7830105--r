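#' Cycle phase permutation surrogate
#'
#' Cuts an unwrapped phase at successive upward crossings of multiples of
#' 2 pi into complete cycles, randomly permutes the cycle segments (as
#' blocks of within-sample phase increments) and re-accumulates them into a
#' continuous unwrapped phase. Intra-cycle dynamics are preserved;
#' inter-cycle timing relations (and hence any phase relation to another
#' oscillator) are destroyed. Leading and trailing partial cycles stay in
#' place and the total phase gain is conserved exactly.
#'
#' @param phase a [phase_series()] containing at least 3 complete cycles.
#' @param seed integer RNG seed.
#' @return a [phase_series()] of the same length, kind, `fs` and `t0`.
#' @export
cycle_phase_permutation <- function(phase, seed) {
  stopifnot(inherits(phase, "phase_series"))
  phi <- phase$phi
  # first sample at or after each upward crossing of k * 2pi; cummax makes
  # the search robust to local non-monotonicity of noisy phases
  phim <- cummax(phi)
  k0 <- ceiling(phi[1] / (2 * pi) + 1e-12)
  kmax <- floor(phim[length(phim)] / (2 * pi))
  if (kmax < k0) stop("phase must contain at least 3 complete cycles")
  cross <- findInterval(2 * pi * seq(k0, kmax), phim, left.open = TRUE) + 1L
  cross <- unique(cross[cross <= length(phi)])
  if (length(cross) < 4L)
    stop("phase must contain at least 3 complete cycles")
  d <- diff(phi)
  cyc <- lapply(seq_len(length(cross) - 1L),
                function(i) d[cross[i]:(cross[i + 1L] - 1L)])
  head_inc <- if (cross[1] > 1L) d[1:(cross[1] - 1L)] else numeric(0)
  tail_inc <- if (cross[length(cross)] <= length(d))
    d[cross[length(cross)]:length(d)] else numeric(0)
  set.seed(seed)
  perm <- sample(length(cyc))
  new_d <- c(head_inc, unlist(cyc[perm]), tail_inc)
  stopifnot(length(new_d) == length(d))
  phase_series(cumsum(c(phi[1], new_d)), phase$fs, kind = phase$kind,
               t0 = phase$t0)
}

#' Surrogate threshold for the coupling strength
#'
#' Re-runs the window inference after cycle-permuting one phase (by default
#' the putative driver, oscillator 2 = respiratory), records the coupling
#' strength into oscillator 1 for each surrogate, and forms the
#' significance threshold `mean + 2 sd` of the surrogate strengths. A
#' measured strength above the threshold indicates coupling beyond what the
#' marginal cycle statistics alone produce.
#'
#' @param phase1,phase2 [phase_series()] (1 = cardiac/driven candidate,
#'   2 = respiratory/driver candidate).
#' @param basis a [build_basis()] object.
#' @param n_surr number of surrogates, >= 2.
#' @param seed integer RNG seed (surrogate `i` uses `seed + i`).
#' @param window_s,propagation,prior_variance passed to [infer_windows()].
#' @param permute which series to permute: `"driver"` (phase2), `"driven"`
#'   (phase1) or `"both"`.
#' @param collect_grids if TRUE also store each surrogate's time-averaged
#'   coupling grid (into oscillator 1).
#' @param grid_M grid side used when `collect_grids = TRUE`.
#' @return a `surrogate_ensemble`: list with `sigma` (per-surrogate median
#'   strength), `original` (the unpermuted strength), `mean`, `sd`,
#'   `threshold = mean + 2 sd`, and optionally `grids`.
#' @export
surrogate_strength_threshold <- function(phase1, phase2,
                                         basis = build_basis(2),
                                         n_surr = 100, seed = 1,
                                         window_s = 50, propagation = 0.2,
                                         prior_variance = 100,
                                         permute = c("driver", "driven",
                                                     "both"),
                                         collect_grids = FALSE,
                                         grid_M = 48) {
  permute <- match.arg(permute)
  if (n_surr < 2) stop("need at least 2 surrogates (sd undefined)")

  run_sigma <- function(p1, p2) {
    res <- infer_windows(p1, p2, basis, window_s = window_s,
                         propagation = propagation,
                         prior_variance = prior_variance)
    subv <- vapply(res$windows,
                   function(w) coupling_strength(
                     coupling_coefficients(w, 1, basis)), 1)
    cf <- rowMeans(vapply(res$windows, function(w) w$coef[, 1],
                          numeric(basis$n_terms)))
    list(sigma = stats::median(subv), mean_coef = cf)
  }

  orig <- run_sigma(phase1, phase2)
  sig <- numeric(n_surr)
  grids <- if (collect_grids) vector("list", n_surr) else NULL
  n_fail <- 0
  for (i in seq_len(n_surr)) {
    p1 <- phase1; p2 <- phase2
    if (permute %in% c("driver", "both"))
      p2 <- cycle_phase_permutation(phase2, seed + i)
    if (permute %in% c("driven", "both"))
      p1 <- cycle_phase_permutation(phase1, seed + n_surr + i)
    res <- try(run_sigma(p1, p2), silent = TRUE)
    if (inherits(res, "try-error")) {
      n_fail <- n_fail + 1; sig[i] <- NA_real_; next
    }
    sig[i] <- res$sigma
    if (collect_grids)
      grids[[i]] <- coupling_grid(res$mean_coef, basis, M = grid_M,
                                  pair = "surrogate")
  }
  if (n_fail > 0.2 * n_surr)
    stop("inference failed in more than 20% of surrogates")
  sig_ok <- sig[!is.na(sig)]
  structure(list(sigma = sig, original = orig$sigma,
                 original_mean_coef = orig$mean_coef,
                 mean = mean(sig_ok), sd = stats::sd(sig_ok),
                 threshold = mean(sig_ok) + 2 * stats::sd(sig_ok),
                 n_surr = n_surr, n_fail = n_fail,
                 grids = if (collect_grids) grids[!is.na(sig)] else NULL),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<surrogate_ensemble> n = %d, original sigma = %.4g, ",
                     "threshold (mean + 2 sd) = %.4g -> %s\n"),
              x$n_surr, x$original, x$threshold,
              if (x$original > x$threshold) "significant" else
                "not significant"))
  invisible(x)
}

#' Mean surrogate coupling grid
#'
#' Element-wise mean of the surrogate coupling grids; near-flat for
#' genuinely destroyed coupling, giving the visual significance floor for
#' coupling-function surfaces.
#'
#' @param ensemble a `surrogate_ensemble` built with `collect_grids = TRUE`.
#' @return a [coupling_grid()].
#' @export
surrogate_mean_grid <- function(ensemble) {
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (is.null(ensemble$grids) || !length(ensemble$grids))
    stop("ensemble carries no grids; rerun with collect_grids = TRUE")
  group_average_grid(ensemble$grids)
}
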