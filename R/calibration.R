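#' Estimate a constant mass offset from reporter ensembles
#'
#' Post-acquisition recalibration for TOF reporter-ion data: every reporter
#' peak matched within `search_tol_ppm` of its theoretical channel m/z
#' contributes a ppm deviation, and the per-file adjustment factor is the
#' median of those deviations (median rather than mean, for robustness to
#' co-isolated interferences). The corrected mass range defaults to the
#' reporter region of the design.
#'
#' @param spectra list of [spectrum()] objects.
#' @param design a [plex_design()].
#' @param search_tol_ppm search window in ppm; ~50 ppm is a typical
#'   pre-calibration TOF reporter window.
#' @param mass_range optional numeric length-2 `c(low, high)` in Th; default
#'   spans the design's reporter masses plus 0.5 Th margin.
#' @return object of class `calibration_model` with fields `offset_ppm`,
#'   `mass_range`, `n_anchors`.
#' @export
estimate_offset <- function(spectra, design, search_tol_ppm = 50,
                            mass_range = NULL) {
  if (search_tol_ppm <= 0) stop("search_tol_ppm must be positive")
  deltas <- numeric(0)
  theo <- stats::setNames(design$mz, design$label)
  for (s in spectra) {
    v <- extract_reporters(s, design, tol_value = search_tol_ppm,
                           tol_unit = "ppm")
    hit <- !is.na(v$matched_mz)
    if (any(hit))
      deltas <- c(deltas,
                  1e6 * (v$matched_mz[hit] - theo[hit]) / theo[hit])
  }
  if (!length(deltas))
    stop("no reporter anchors matched within ", search_tol_ppm, " ppm")
  if (is.null(mass_range))
    mass_range <- range(design$mz) + c(-0.5, 0.5)
  calibration_model(offset_ppm = stats::median(deltas),
                    mass_range = mass_range,
                    n_anchors = length(deltas))
}

#' Construct a calibration model
#'
#' @param offset_ppm constant ppm offset of observed over theoretical mass.
#' @param mass_range numeric length-2, m/z range (Th) the correction applies
#'   to.
#' @param n_anchors number of matched reporter peaks supporting the estimate.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(offset_ppm, mass_range, n_anchors = 1L) {
  stopifnot(is.numeric(offset_ppm), length(offset_ppm) == 1L,
            length(mass_range) == 2L, mass_range[1] < mass_range[2],
            n_anchors >= 1L)
  structure(
    list(offset_ppm = as.numeric(offset_ppm),
         mass_range = as.numeric(mass_range),
         n_anchors = as.integer(n_anchors)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> offset %+.3f ppm over m/z [%.3f, %.3f] (%d anchors)\n",
    x$offset_ppm, x$mass_range[1], x$mass_range[2], x$n_anchors))
  invisible(x)
}

#' Apply a mass calibration to a spectrum
#'
#' Every peak inside the model's mass range has its m/z replaced by
#' `mz / (1 + offset_ppm * 1e-6)`; peaks outside the range, peak count,
#' ordering and intensities are untouched.
#'
#' @param spec a [spectrum()].
#' @param model a [calibration_model()].
#' @return corrected `spectrum`.
#' @export
apply_calibration <- function(spec, model) {
  stopifnot(inherits(model, "calibration_model"))
  inside <- spec$mz >= model$mass_range[1] & spec$mz <= model$mass_range[2]
  spec$mz[inside] <- spec$mz[inside] / (1 + model$offset_ppm * 1e-6)
  if (is.unsorted(spec$mz)) {  # a peak at a range boundary can cross it
    o <- order(spec$mz)
    spec$mz <- spec$mz[o]
    spec$intensity <- spec$intensity[o]
  }
  spec
}

#' Calibrate a whole run
#'
#' Convenience wrapper: estimate the per-file offset and rewrite all spectra.
#'
#' @inheritParams estimate_offset
#' @return list with `spectra` (corrected) and `model`.
#' @export
calibrate_run <- function(spectra, design, search_tol_ppm = 50,
                          mass_range = NULL) {
  model <- estimate_offset(spectra, design, search_tol_ppm, mass_range)
  list(spectra = lapply(spectra, apply_calibration, model = model),
       model = model)
}
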