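#' Reporter-presence MS2 filtering (DIDAR-style)
#'
#' Retains an MS2 spectrum iff at least one of the required single-cell
#' channels has a peak within `tol_da` of its exact reporter mass — the
#' pre-analysis QC step that discards spectra carrying no single-cell signal.
#' Optionally writes the retained spectra to a new MGF whose file name gets
#' the prefix `"Filtered"`.
#'
#' @param spectra list of [spectrum()] objects.
#' @param design a [plex_design()].
#' @param required_channels channel labels, typically the single-cell wells
#'   (e.g. 127N-131N); defaults to all `single_cell` channels of the design.
#' @param tol_da mass tolerance in Da (default 0.005).
#' @param run_id identifier recorded in the summary.
#' @param out_path optional MGF path; the basename is prefixed with
#'   `"Filtered"` before writing.
#' @return list with `spectra` (retained) and `summary`, a `run_qc_summary`:
#'   `run_id`, `channel_counts` (named, spectra with a matched reporter per
#'   design channel), `roles`, `total`, `retained`, `pass` (NA until
#'   [flag_failed_runs()]).
#' @export
filter_by_reporter_presence <- function(spectra, design,
                                        required_channels = NULL,
                                        tol_da = 0.005,
                                        run_id = "run",
                                        out_path = NULL) {
  if (is.null(required_channels))
    required_channels <- design$label[design$role == "single_cell"]
  if (!length(required_channels)) stop("required channel set is empty")
  bad <- setdiff(required_channels, design$label)
  if (length(bad))
    stop("required channels not in design: ", paste(bad, collapse = ", "))
  counts <- stats::setNames(integer(nrow(design)), design$label)
  cell_labels <- design$label[design$role == "single_cell"]
  cell_signal_n <- 0L
  keep <- logical(length(spectra))
  for (i in seq_along(spectra)) {
    v <- extract_reporters(spectra[[i]], design, tol_value = tol_da,
                           tol_unit = "Da")
    hit <- !is.na(v$intensity)
    counts <- counts + hit
    keep[i] <- any(hit[required_channels])
    if (length(cell_labels) && any(hit[cell_labels]))
      cell_signal_n <- cell_signal_n + 1L
  }
  retained <- spectra[keep]
  if (!is.null(out_path)) {
    path <- file.path(dirname(out_path),
                      paste0("Filtered", basename(out_path)))
    write_mgf(retained, path)
  }
  summary <- structure(
    list(run_id = run_id,
         channel_counts = counts,
         roles = stats::setNames(design$role, design$label),
         cell_signal_n = cell_signal_n,
         total = length(spectra),
         retained = length(retained),
         pass = NA),
    class = "run_qc_summary"
  )
  list(spectra = retained, summary = summary)
}

#' @export
print.run_qc_summary <- function(x, ...) {
  cat(sprintf("<run_qc_summary '%s'> %d/%d MS2 retained; pass=%s\n",
              x$run_id, x$retained, x$total, format(x$pass)))
  print(x$channel_counts)
  invisible(x)
}

#' Blank-based run rejection
#'
#' A run passes QC only when the number of spectra carrying signal in any
#' single-cell channel exceeds `factor` times the number of spectra with
#' signal in the method-blank channel — the 3x-blank rule. Counts are
#' spectrum counts, not summed intensities.
#'
#' @param summaries list of `run_qc_summary` objects from
#'   [filter_by_reporter_presence()].
#' @param blank_channel label of the method blank (e.g. `"126"`).
#' @param factor positive multiplier (default 3).
#' @return the summaries with `pass` set.
#' @export
flag_failed_runs <- function(summaries, blank_channel = "126", factor = 3) {
  if (factor <= 0) stop("factor must be positive")
  lapply(summaries, function(s) {
    if (!blank_channel %in% names(s$channel_counts))
      stop("unknown blank channel: ", blank_channel)
    s$pass <- s$cell_signal_n > factor * s$channel_counts[[blank_channel]]
    s
  })
}

#' Top-k-per-window peak binning
#'
#' Spectrum-complexity reduction: the m/z axis is cut into fixed, contiguous
#' half-open windows `[0, w), [w, 2w), ...` anchored at zero, and only the
#' `k` most intense peaks survive in each window (ties broken toward lower
#' m/z). The standard setting retains the 12 most intense fragment ions per
#' 100 Da window.
#'
#' @param spec a [spectrum()].
#' @param k peaks kept per window (default 12).
#' @param window_da window width in Da (default 100).
#' @return filtered `spectrum`, sorted by m/z.
#' @export
bin_top_k <- function(spec, k = 12, window_da = 100) {
  if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
  if (window_da <= 0) stop("window_da must be positive")
  if (!length(spec$mz)) return(spec)
  bin <- floor(spec$mz / window_da)
  keep <- unlist(lapply(split(seq_along(spec$mz), bin), function(ix) {
    ix[order(-spec$intensity[ix], spec$mz[ix])][seq_len(min(k, length(ix)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  spec$mz <- spec$mz[keep]
  spec$intensity <- spec$intensity[keep]
  spec
}

#' Tabulate run QC summaries
#'
#' @param summaries list of `run_qc_summary` objects.
#' @return data.frame, one row per run, with total/retained/blank counts and
#'   pass flags; suitable for writing as delimited text.
#' @export
qc_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(run_id = s$run_id, total = s$total, retained = s$retained,
               blank_count = if ("126" %in% names(s$channel_counts))
                 s$channel_counts[["126"]] else NA_integer_,
               pass = s$pass, stringsAsFactors = FALSE)
  }))
}
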