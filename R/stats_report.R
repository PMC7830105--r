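#' Friedman test across protocol stages
#'
#' Non-parametric repeated-measures comparison of one measure (e.g. coupling
#' strength) across the protocol stages, subjects as blocks. Wraps the
#' classical Friedman chi-square statistic on within-subject ranks with
#' average-rank ties and the chi-square approximation for the p-value.
#'
#' @param matrix numeric subjects x stages matrix, complete (no NA), with at
#'   least 2 subjects and 3 stages (the chi-square approximation is invalid
#'   below 3 treatments).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
friedman_stage_test <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("matrix must be complete (no missing cells)")
  if (ncol(matrix) < 3) stop("need at least 3 stages")
  if (nrow(matrix) < 2) stop("need at least 2 subjects")
  ft <- stats::friedman.test(matrix)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat) && all(apply(matrix, 1, stats::var) == 0)) {
    # every subject ties all stages: no evidence of any difference
    stat <- 0; p <- 1
  }
  list(statistic = stat, df = unname(ft$parameter), p_value = p)
}

#' Pairwise post hoc comparison after a significant Friedman test
#'
#' Tukey-type honest-significant-difference comparison on within-subject
#' rank sums (Nemenyi critical values): stages `i`, `j` differ when
#' `|Rbar_i - Rbar_j| > q(1 - alpha, k, Inf) / sqrt(2) *
#' sqrt(k (k + 1) / (6 n))`, with `Rbar` the mean ranks, `k` stages and `n`
#' subjects. Runs only when the Friedman p-value is below `alpha`; otherwise
#' returns an empty set with a note.
#'
#' @param matrix numeric subjects x stages matrix (complete).
#' @param alpha significance level (default 0.05).
#' @return data frame with columns `stage1`, `stage2`, `diff` (mean-rank
#'   difference), `critical`, `significant`; attribute `"note"` explains an
#'   empty result. Only significant pairs are returned in the data frame
#'   when the gate passes.
#' @export
posthoc_pairwise <- function(matrix, alpha = 0.05) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("matrix must be complete (no missing cells)")
  k <- ncol(matrix); n <- nrow(matrix)
  labs <- colnames(matrix)
  if (is.null(labs)) labs <- paste0("S", seq_len(k))
  empty <- data.frame(stage1 = character(0), stage2 = character(0),
                      diff = numeric(0), critical = numeric(0),
                      significant = logical(0))
  if (alpha <= 0) return(structure(empty, note = "alpha <= 0"))
  ft <- friedman_stage_test(matrix)
  if (ft$p_value >= alpha)
    return(structure(empty,
                     note = sprintf("Friedman p = %.3g >= alpha; no post hoc",
                                    ft$p_value)))
  ranks <- t(apply(matrix, 1, rank))
  rbar <- colMeans(ranks)
  crit <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) *
    sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  out <- data.frame(stage1 = labs[pairs[1, ]], stage2 = labs[pairs[2, ]],
                    diff = abs(rbar[pairs[1, ]] - rbar[pairs[2, ]]),
                    critical = crit)
  out$significant <- out$diff > crit
  rownames(out) <- NULL
  structure(out[out$significant, , drop = FALSE], note = "", all = out)
}

#' Write the analysis report bundle
#'
#' Serialises a pipeline result (see [analyze_recording()]) to CSV tables:
#' per directed pair a per-window table (midtime, stage, strengths, D), a
#' per-stage median table, and the stage-averaged coupling grids as M x M
#' matrices; plus a JSON run manifest (settings, seed, package version).
#'
#' @param analysis result of [analyze_recording()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
build_report <- function(analysis, out_dir) {
  if (!inherits(analysis, "pair_analysis_set"))
    stop("analysis must be the result of analyze_recording()")
  if (!length(analysis$pairs)) stop("empty analysis: nothing to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(analysis$pairs)) {
    pa <- analysis$pairs[[nm]]
    safe <- gsub("[^A-Za-z0-9_]+", "_", nm)
    utils::write.csv(pa$windows,
                     file.path(out_dir, paste0("windows_", safe, ".csv")),
                     row.names = FALSE)
    med <- data.frame(stage = names(pa$stage_sigma),
                      sigma_median = unname(pa$stage_sigma),
                      D_median = unname(pa$stage_D))
    utils::write.csv(med,
                     file.path(out_dir, paste0("stages_", safe, ".csv")),
                     row.names = FALSE)
    for (st in names(pa$stage_grids)) {
      utils::write.table(pa$stage_grids[[st]]$values,
                         file.path(out_dir,
                                   paste0("grid_", safe, "_", st, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  manifest <- list(pairs = names(analysis$pairs),
                   config = analysis$config[!vapply(analysis$config, is.null,
                                                    TRUE)],
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version =
                     as.character(utils::packageVersion("phasecf")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
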