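#' Coupling function on the 2pi x 2pi grid
#'
#' Evaluates `q(phi1, phi2) = sum_k c_k Phi_k(phi1, phi2)` over all
#' non-constant basis terms on a uniform M x M grid over `[0, 2pi)^2`
#' (rows index `phi1`, columns `phi2`).
#'
#' @param coefficients full coefficient vector aligned to `basis` (the
#'   constant term is ignored), e.g. one column of a window estimate's
#'   `coef`.
#' @param basis a [build_basis()] object.
#' @param M grid side, >= 8 (default 100).
#' @param pair,stage,subject optional metadata labels.
#' @return a `coupling_grid`: list with `values` (M x M), `M`, and metadata.
#' @export
coupling_grid <- function(coefficients, basis, M = 100, pair = NA,
                          stage = NA, subject = NA) {
  stopifnot(inherits(basis, "fourier_basis"),
            length(coefficients) == basis$n_terms)
  if (M < 8) stop("grid size M must be at least 8")
  ang <- seq(0, 2 * pi, length.out = M + 1)[seq_len(M)]
  tb <- basis$terms
  vals <- matrix(0, M, M)
  for (j in 2:basis$n_terms) {
    if (coefficients[j] == 0) next
    A <- outer(tb$k1[j] * ang, tb$k2[j] * ang, `+`)
    vals <- vals + coefficients[j] * (if (tb$type[j] == "sin") sin(A) else cos(A))
  }
  structure(list(values = vals, M = M, pair = pair, stage = stage,
                 subject = subject), class = "coupling_grid")
}

#' Directionality index
#'
#' `D = (c2 - c1) / (c1 + c2)` where `c_i` is the aggregate coupling norm
#' acting ON oscillator `i`. With oscillator 1 = cardiac and 2 =
#' respiratory, `D` in `[-1, 0)` means the respiratory oscillation
#' predominantly drives the cardiac one, `D` in `(0, 1]` the reverse.
#'
#' @param c1,c2 non-negative coupling norms (vectors allowed, recycled).
#' @return numeric in `[-1, 1]`; both-zero inputs are an error (the
#'   direction is undefined, never reported as 0).
#' @export
directionality <- function(c1, c2) {
  if (any(c1 < 0) || any(c2 < 0)) stop("coupling norms must be >= 0")
  s <- c1 + c2
  if (any(s == 0)) stop("c1 = c2 = 0: direction undefined")
  (c2 - c1) / s
}

#' Coupling strength
#'
#' Euclidean norm of a coupling-coefficient subvector (square root of the
#' sum of squared Fourier coefficients through which one phase enters the
#' other's dynamics).
#'
#' @param coefficients numeric vector, typically from
#'   [coupling_coefficients()].
#' @export
coupling_strength <- function(coefficients) sqrt(sum(coefficients ^ 2))

#' Polar similarity of two coupling functions
#'
#' `|rho| = |<q1~ q2~>| / (|q1~| |q2~|) x 100`, where the tilde removes the
#' grid mean and `|.|` is the root mean square over the 2pi x 2pi grid.
#' Quantifies whether two interactions share the same functional form,
#' independent of their amplitudes; range 0-100%.
#'
#' @param grid1,grid2 [coupling_grid()]s of equal size; each must be
#'   non-constant.
#' @return similarity in percent.
#' @export
polar_similarity <- function(grid1, grid2) {
  stopifnot(inherits(grid1, "coupling_grid"), inherits(grid2, "coupling_grid"))
  if (grid1$M != grid2$M) stop("grids must have equal size")
  q1 <- grid1$values - mean(grid1$values)
  q2 <- grid2$values - mean(grid2$values)
  n1 <- sqrt(mean(q1 ^ 2)); n2 <- sqrt(mean(q2 ^ 2))
  if (n1 == 0 || n2 == 0) stop("constant grid: similarity undefined")
  abs(mean(q1 * q2)) / (n1 * n2) * 100
}

#' Aggregate per-window values by protocol stage
#'
#' Assigns each window to the stage containing its midtime (half-open
#' `[start, end)` rule) and aggregates with the given statistic. Stages with
#' no windows get `NA` and a warning.
#'
#' @param values numeric per-window values.
#' @param midtimes numeric per-window midtimes, seconds.
#' @param protocol a [stage_protocol()].
#' @param statistic `"median"` (default) or `"mean"`.
#' @return named numeric vector, one entry per protocol stage.
#' @export
stage_aggregate <- function(values, midtimes, protocol,
                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) == length(midtimes),
            inherits(protocol, "stage_protocol"))
  fun <- if (statistic == "median") stats::median else mean
  out <- stats::setNames(rep(NA_real_, nrow(protocol)), protocol$label)
  for (i in seq_len(nrow(protocol))) {
    sel <- midtimes >= protocol$start_s[i] & midtimes < protocol$end_s[i]
    if (!any(sel)) {
      warning("stage '", protocol$label[i], "' has no windows")
    } else out[i] <- fun(values[sel])
  }
  out
}

#' Stage membership of window midtimes
#'
#' @param midtimes numeric midtimes, seconds.
#' @param protocol a [stage_protocol()].
#' @return character vector of stage labels (`NA` outside all stages).
#' @export
stage_of_midtime <- function(midtimes, protocol) {
  out <- rep(NA_character_, length(midtimes))
  for (i in seq_len(nrow(protocol))) {
    sel <- midtimes >= protocol$start_s[i] & midtimes < protocol$end_s[i]
    out[sel] <- protocol$label[i]
  }
  out
}

#' Element-wise mean of coupling grids
#'
#' Used for group-averaged coupling functions (average over windows within a
#' stage per subject, then across subjects).
#'
#' @param grids non-empty list of [coupling_grid()]s of equal size.
#' @return a [coupling_grid()] with the element-wise mean and the metadata
#'   of the first grid.
#' @export
group_average_grid <- function(grids) {
  if (!length(grids)) stop("empty grid list")
  stopifnot(all(vapply(grids, inherits, TRUE, "coupling_grid")))
  M <- grids[[1]]$M
  if (!all(vapply(grids, function(g) g$M, 1) == M))
    stop("grids must have equal size")
  vals <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
  structure(list(values = vals, M = M, pair = grids[[1]]$pair,
                 stage = grids[[1]]$stage, subject = grids[[1]]$subject),
            class = "coupling_grid")
}
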