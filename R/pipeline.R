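#' Directed respiratory-to-cardiac pair enumeration
#'
#' The study analyses, for each channel, the coupling from the respiratory
#' to the cardiac component within the same signal, plus all cross-signal
#' combinations: with channels BP, SAS_LEFT, SAS_RIGHT this yields 9
#' directed pairs (3 within-signal, BP_r to SAS_c x2, SAS_r to BP_c x2,
#' SAS_r to SAS_c x2).
#'
#' @param channels character vector of channel names.
#' @return data frame with columns `resp_channel`, `card_channel`, `label`.
#' @export
directed_pairs <- function(channels = c("BP", "SAS_LEFT", "SAS_RIGHT")) {
  g <- expand.grid(resp_channel = channels, card_channel = channels,
                   stringsAsFactors = FALSE)
  g$label <- paste0(g$resp_channel, "r->", g$card_channel, "c")
  g[order(g$resp_channel != g$card_channel), ]
}

#' Run the full coupling analysis on one recording
#'
#' For every requested directed pair: extract respiratory and cardiac
#' phases (see [extract_phases()]), run windowed dynamical Bayesian
#' inference with cardiac as oscillator 1 and respiratory as oscillator 2,
#' and compute per-window directed strengths and directionality, per-stage
#' medians, and stage-averaged coupling grids (mean coefficient vector over
#' the windows of a stage, evaluated on the torus grid).
#'
#' @param record a [signal_record()].
#' @param protocol a [stage_protocol()].
#' @param config a [run_config()].
#' @param pairs optional subset of pair labels (as in [directed_pairs()]);
#'   default all pairs over the record's channels.
#' @return a `pair_analysis_set`: list with `pairs` (per-pair list of
#'   `windows` data frame, `stage_sigma`, `stage_D`, `stage_coef`,
#'   `stage_grids`), `protocol`, `config`.
#' @export
analyze_recording <- function(record, protocol, config = run_config(),
                              pairs = NULL) {
  stopifnot(inherits(record, "signal_record"),
            inherits(protocol, "stage_protocol"))
  chans <- colnames(record$samples)
  tab <- directed_pairs(chans)
  if (!is.null(pairs)) {
    bad <- setdiff(pairs, tab$label)
    if (length(bad)) stop("unknown pair label(s): ",
                          paste(bad, collapse = ", "))
    tab <- tab[tab$label %in% pairs, ]
  }
  need <- unique(c(tab$resp_channel, tab$card_channel))
  phases <- lapply(stats::setNames(need, need),
                   function(ch) extract_phases(record, ch, config))
  basis <- build_basis(config$fourier_order)

  out <- list()
  for (i in seq_len(nrow(tab))) {
    p_r <- phases[[tab$resp_channel[i]]]$respiratory
    p_c <- phases[[tab$card_channel[i]]]$cardiac
    res <- infer_windows(p_c, p_r, basis, window_s = config$window_s,
                         propagation = config$propagation,
                         prior_variance = config$prior_variance,
                         tol = config$tol, max_iter = config$max_iter)
    wt <- window_table(res)
    wt$stage <- stage_of_midtime(wt$midtime, protocol)
    stage_sigma <- stage_aggregate(wt$strength_in1, wt$midtime, protocol,
                                   "median")
    stage_D <- stage_aggregate(wt$D, wt$midtime, protocol, "median")
    stage_coef <- list(); stage_grids <- list()
    cf_mat <- vapply(res$windows, function(w) w$coef[, 1],
                     numeric(basis$n_terms))
    for (st in protocol$label) {
      sel <- !is.na(wt$stage) & wt$stage == st
      if (!any(sel)) next
      cf <- rowMeans(cf_mat[, sel, drop = FALSE])
      stage_coef[[st]] <- cf
      stage_grids[[st]] <- coupling_grid(cf, basis, M = config$grid_size,
                                         pair = tab$label[i], stage = st)
    }
    out[[tab$label[i]]] <- list(windows = wt, stage_sigma = stage_sigma,
                                stage_D = stage_D, stage_coef = stage_coef,
                                stage_grids = stage_grids,
                                result = res)
  }
  structure(list(pairs = out, protocol = protocol,
                 config = unclass(config), basis = basis),
            class = "pair_analysis_set")
}

#' Simulate and analyse a synthetic subject cohort
#'
#' Draws per-subject generator parameters (cardiac frequency, baseline
#' respiratory frequency, coupling gain) around the protocol defaults,
#' simulates each subject's four-stage recording, runs the full pipeline,
#' and collects per-subject stage medians of the coupling strength and the
#' polar similarity of each stage's coupling function to baseline stage A.
#'
#' @param n_subjects number of subjects (study group size: 20).
#' @param config a [run_config()].
#' @param seed integer seed; subject `i` uses `seed * 1000 + i`.
#' @param pairs pair labels to analyse (default the within-BP pair, the
#'   primary respiratory sinus arrhythmia readout).
#' @param protocol a [protocol_spec()].
#' @param fs sampling rate, Hz.
#' @return list with `sigma` (subjects x stages matrix of per-stage median
#'   coupling strength), `similarity` (subjects x stages matrix of percent
#'   similarity to stage A, per pair in a named list when several pairs),
#'   `per_subject` details.
#' @export
analyze_cohort <- function(n_subjects = 20, config = run_config(), seed = 1,
                           pairs = "BPr->BPc", protocol = protocol_spec(),
                           fs = 50) {
  stage_labs <- protocol$label
  sig <- list(); sim <- list()
  for (p in pairs) {
    sig[[p]] <- matrix(NA_real_, n_subjects, length(stage_labs),
                       dimnames = list(NULL, stage_labs))
    sim[[p]] <- matrix(NA_real_, n_subjects, length(stage_labs),
                       dimnames = list(NULL, stage_labs))
  }
  per_subject <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- seed * 1000 + s
    set.seed(sseed)
    f_card <- stats::rnorm(3, 1.0, 0.05)
    f_card <- pmin(pmax(f_card, 0.8), 1.4)
    f_resp0 <- min(max(stats::rnorm(1, 0.25, 0.02), 0.18), 0.33)
    gain <- 0.2 * exp(stats::rnorm(1, 0, 0.15))
    proto_s <- protocol
    proto_s$resp_freq_hz[proto_s$resp_freq_hz > 0.15] <- f_resp0
    sim_out <- simulate_protocol(proto_s, fs = fs, seed = sseed + 1,
                                 base_gain = gain,
                                 cardiac_freq_hz = f_card)
    an <- analyze_recording(sim_out$record, sim_out$protocol, config,
                            pairs = pairs)
    for (p in pairs) {
      pa <- an$pairs[[p]]
      sig[[p]][s, names(pa$stage_sigma)] <- pa$stage_sigma
      gA <- pa$stage_grids[["A"]]
      for (st in names(pa$stage_grids)) {
        sim[[p]][s, st] <- if (!is.null(gA))
          polar_similarity(pa$stage_grids[[st]], gA) else NA_real_
      }
    }
    per_subject[[s]] <- list(seed = sseed, gain = gain, f_card = f_card,
                             f_resp0 = f_resp0,
                             stage_sigma = lapply(an$pairs, `[[`,
                                                  "stage_sigma"))
  }
  if (length(pairs) == 1L) { sig <- sig[[1]]; sim <- sim[[1]] }
  list(sigma = sig, similarity = sim, per_subject = per_subject,
       protocol = protocol, pairs = pairs)
}
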