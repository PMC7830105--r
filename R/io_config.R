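#' Multichannel signal record
#'
#' Container for a uniformly sampled multichannel recording (e.g. blood
#' pressure and left/right subarachnoid-space width), with its sampling rate
#' and start time.
#'
#' @param samples numeric matrix (rows = samples, columns = channels) with
#'   column names, or a data frame coercible to one.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds (default 0).
#' @return an object of class `signal_record`: a list with elements
#'   `samples`, `fs`, `t0`.
#' @export
signal_record <- function(samples, fs, t0 = 0) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1,
                                               dimnames = list(NULL, "X1"))
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (is.null(colnames(samples)) || anyDuplicated(colnames(samples)))
    stop("samples must have unique channel names")
  if (ncol(samples) < 1L || nrow(samples) < 1L)
    stop("record must contain at least one channel and one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (any(!is.finite(samples)))
    stop("record contains non-finite samples; interpolate gaps on ingestion")
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channels x %d samples, fs = %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(colnames(x$samples), collapse = ", "), "\n")
  invisible(x)
}

record_duration <- function(record) nrow(record$samples) / record$fs

record_times <- function(record) {
  record$t0 + (seq_len(nrow(record$samples)) - 1) / record$fs
}

#' Stage protocol
#'
#' Ordered set of labelled protocol stages as half-open time intervals
#' `[start_s, end_s)`. The study design uses four stages: (A) baseline free
#' breathing, (B) paced breathing at 6 breaths/min, (C) paced breathing at
#' 6 breaths/min against inspiratory resistance, (D) recovery.
#'
#' @param labels character vector of unique stage labels.
#' @param start_s,end_s numeric stage boundaries in seconds.
#' @return a `stage_protocol` data frame with columns `label`, `start_s`,
#'   `end_s`.
#' @export
stage_protocol <- function(labels, start_s, end_s) {
  if (length(labels) != length(start_s) || length(labels) != length(end_s))
    stop("labels, start_s and end_s must have equal length")
  if (anyDuplicated(labels)) stop("stage labels must be unique")
  if (length(labels) > 0L) {
    if (any(end_s <= start_s)) stop("each stage must have end_s > start_s")
    if (is.unsorted(start_s, strictly = TRUE))
      stop("stages must be ordered in time")
    if (any(start_s[-1] < end_s[-length(end_s)] - 1e-9))
      stop("stages must not overlap")
  }
  structure(data.frame(label = as.character(labels), start_s = start_s,
                       end_s = end_s, stringsAsFactors = FALSE),
            class = c("stage_protocol", "data.frame"))
}

#' Run configuration
#'
#' All tunable parameters of the analysis pipeline with their defaults.
#' Frequency bands in Hz, windows in seconds.
#'
#' @param resp_band respiratory bandpass edges, default `c(0.1, 0.6)` Hz.
#' @param cardiac_band cardiac bandpass edges, default `c(0.6, 2)` Hz.
#' @param filter_order Butterworth order per pass (applied forward-backward,
#'   so the effective order doubles). Default 4: when both modes are read
#'   from one composite observable, the cardiac component must be suppressed
#'   by much more than 20 dB in the respiratory band, or its leakage imprints
#'   a spurious beat-frequency term on the respiratory protophase velocity.
#' @param detrend_window_s moving-average detrend window, seconds.
#' @param edge_trim_s seconds discarded from each end of extracted phases
#'   (filter/analytic-signal edge effects).
#' @param window_s inference window length, seconds, non-overlapping.
#' @param fourier_order order K of the Fourier expansion of the phase model.
#' @param grid_size side M of the 2pi x 2pi coupling-function grid.
#' @param n_surrogates number of cycle phase permutation surrogates.
#' @param propagation propagation constant for inter-window prior diffusion
#'   (0 = independent windows).
#' @param proto_harmonics number of harmonics in the protophase-to-phase
#'   transformation.
#' @param prior_variance initial prior variance per coefficient.
#' @param tol,max_iter convergence control of the window inference loop.
#' @param seed optional integer seed recorded with the run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(resp_band = c(0.1, 0.6), cardiac_band = c(0.6, 2),
                       filter_order = 4, detrend_window_s = 30,
                       edge_trim_s = 10, window_s = 50, fourier_order = 2,
                       grid_size = 100, n_surrogates = 100, propagation = 0.2,
                       proto_harmonics = 48, prior_variance = 100,
                       tol = 1e-5, max_iter = 100, seed = NULL) {
  cfg <- list(resp_band = resp_band, cardiac_band = cardiac_band,
              filter_order = filter_order, detrend_window_s = detrend_window_s,
              edge_trim_s = edge_trim_s, window_s = window_s,
              fourier_order = fourier_order, grid_size = grid_size,
              n_surrogates = n_surrogates, propagation = propagation,
              proto_harmonics = proto_harmonics,
              prior_variance = prior_variance, tol = tol,
              max_iter = max_iter, seed = seed)
  stopifnot(cfg$filter_order >= 1, cfg$detrend_window_s > 0,
            cfg$window_s > 0, cfg$fourier_order >= 1, cfg$grid_size >= 8,
            cfg$propagation >= 0, cfg$prior_variance > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Keys map 1:1 to the arguments of [run_config()]; missing keys take the
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Read a recording from delimited text
#'
#' Expects one header row of channel names, optionally preceded by comment
#' lines of the form `# fs=<Hz>` and `# t0=<s>`. Comma and tab separators are
#' auto-detected from the header. Interior runs of missing values up to
#' `max_gap_s` seconds are linearly interpolated; longer gaps, or missing
#' values at the record edges, are an error.
#'
#' @param path path to the CSV/TSV file.
#' @param fs sampling rate in Hz; required if the file carries no
#'   `# fs=` metadata line.
#' @param max_gap_s longest interior gap (seconds) repaired by linear
#'   interpolation.
#' @return a [signal_record()].
#' @export
read_recording <- function(path, fs = NULL, max_gap_s = 1) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("recording file has no data rows")

  file_fs <- NA_real_; t0 <- 0
  for (m in meta) {
    mm <- regmatches(m, regexec("fs\\s*=\\s*([0-9.eE+-]+)", m))[[1]]
    if (length(mm) == 2L) file_fs <- as.numeric(mm[2])
    mm <- regmatches(m, regexec("t0\\s*=\\s*([0-9.eE+-]+)", m))[[1]]
    if (length(mm) == 2L) t0 <- as.numeric(mm[2])
  }
  if (is.null(fs)) fs <- if (is.finite(file_fs)) file_fs else NULL
  if (is.null(fs))
    stop("sampling rate not given: no '# fs=' metadata line and no fs argument")

  sep <- if (grepl("\t", body[1])) "\t" else ","
  header <- trimws(strsplit(body[1], sep, fixed = TRUE)[[1]])
  cells <- strsplit(body[-1], sep, fixed = TRUE)
  nc <- length(header)
  bad <- which(vapply(cells, length, 1L) != nc)
  if (length(bad))
    stop("ragged row(s) in recording file, first at data row ", bad[1])
  mat <- matrix(NA_real_, nrow = length(cells), ncol = nc,
                dimnames = list(NULL, header))
  for (j in seq_len(nc)) {
    col_chr <- trimws(vapply(cells, `[[`, "", j))
    suppressWarnings(col <- as.numeric(col_chr))
    miss <- is.na(col) & !(tolower(col_chr) %in% c("na", "nan", ""))
    if (any(miss))
      stop("non-numeric cell in column '", header[j], "' at data row ",
           which(miss)[1])
    mat[, j] <- col
  }
  mat <- apply(mat, 2, repair_gaps, fs = fs, max_gap_s = max_gap_s)
  dimnames(mat) <- list(NULL, header)
  signal_record(mat, fs = fs, t0 = t0)
}

# Linear interpolation of interior NA runs no longer than max_gap_s seconds.
repair_gaps <- function(x, fs, max_gap_s) {
  x[!is.finite(x)] <- NA_real_
  if (!anyNA(x)) return(x)
  if (is.na(x[1]) || is.na(x[length(x)]))
    stop("missing values at the record edges cannot be interpolated")
  r <- rle(is.na(x))
  if (max(r$lengths[r$values]) > max_gap_s * fs)
    stop("gap longer than ", max_gap_s, " s; refusing to interpolate")
  idx <- which(!is.na(x))
  stats::approx(idx, x[idx], xout = seq_along(x))$y
}

#' Write a recording as delimited text
#'
#' Writes `# fs=` and `# t0=` metadata lines, a header of channel names, and
#' one CSV row per sample at 12 significant digits, so that
#' [read_recording()] inverts it at that precision.
#'
#' @param record a [signal_record()].
#' @param path output file path.
#' @export
write_recording <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.12g", record$fs),
               sprintf("# t0=%.12g", record$t0),
               paste(colnames(record$samples), collapse = ",")), con)
  utils::write.table(format(record$samples, digits = 12, trim = TRUE,
                            scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a stage protocol CSV
#'
#' Plain CSV with columns `label,start_s,end_s`.
#'
#' @param path file path.
#' @return for `read_protocol`, a [stage_protocol()].
#' @export
read_protocol <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(df)))
    stop("protocol CSV must have columns label,start_s,end_s")
  stage_protocol(df$label, df$start_s, df$end_s)
}

#' @rdname read_protocol
#' @param protocol a [stage_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  utils::write.csv(as.data.frame(protocol), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Segment a recording into protocol stages
#'
#' Splits a record along the stage intervals, assigning each sample by the
#' half-open convention `[start_s, end_s)` on its timestamp.
#'
#' @param record a [signal_record()].
#' @param protocol a [stage_protocol()].
#' @return a named list of `signal_record`s, one per stage, in protocol
#'   order. Each sub-record keeps the original `fs` and gets `t0` equal to
#'   the time of its first sample.
#' @export
segment_stages <- function(record, protocol) {
  stopifnot(inherits(record, "signal_record"),
            inherits(protocol, "stage_protocol"))
  dur <- record$t0 + record_duration(record)
  out <- list()
  tt <- record_times(record)
  for (i in seq_len(nrow(protocol))) {
    st <- protocol$start_s[i]; en <- protocol$end_s[i]
    if (en > dur + 1e-9)
      stop("stage '", protocol$label[i], "' ends at ", en,
           " s, beyond the record end (", dur, " s)")
    keep <- tt >= st - 1e-9 & tt < en - 1e-9
    out[[protocol$label[i]]] <-
      signal_record(record$samples[keep, , drop = FALSE], fs = record$fs,
                    t0 = tt[which(keep)[1]])
  }
  out
}
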