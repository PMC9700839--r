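#' Extract reporter-ion intensities from one spectrum
#'
#' For each channel of the design, records the most intense peak within the
#' mass tolerance of the channel's theoretical m/z. A single peak may satisfy
#' at most one channel: peaks falling inside several windows are assigned to
#' the channel with the nearest theoretical m/z. In-window ties are broken by
#' intensity, then by proximity. Channels with no in-window peak — and peaks
#' of zero intensity — are reported as missing, matching the
#' minimum-reporter-intensity filtering philosophy of downstream processing.
#'
#' @param spec a [spectrum()].
#' @param design a [plex_design()].
#' @param tol_value tolerance magnitude (default 0.005).
#' @param tol_unit `"Da"` (default, per the standard 0.005 Da reporter
#'   window) or `"ppm"`.
#' @return object of class `reporter_vector`: list with `spectrum_id`,
#'   named numeric `intensity` and `matched_mz` (NA = missing).
#' @export
extract_reporters <- function(spec, design, tol_value = 0.005,
                              tol_unit = c("Da", "ppm")) {
  tol_unit <- match.arg(tol_unit)
  if (!is.numeric(tol_value) || tol_value <= 0)
    stop("tol_value must be positive")
  theo <- design$mz
  labels <- design$label
  width <- if (tol_unit == "ppm") theo * tol_value * 1e-6
           else rep(tol_value, length(theo))
  intensity <- stats::setNames(rep(NA_real_, length(theo)), labels)
  matched <- stats::setNames(rep(NA_real_, length(theo)), labels)
  if (length(spec$mz)) {
    # candidate (peak, channel) pairs; each peak goes to its nearest channel
    for (k in seq_along(theo)) {
      in_win <- which(abs(spec$mz - theo[k]) <= width[k])
      if (!length(in_win)) next
      dists <- abs(outer(spec$mz[in_win], theo, "-"))
      inside <- sweep(dists, 2, width, "<=")
      dists[!inside] <- Inf
      owner <- apply(dists, 1L, which.min)
      mine <- in_win[owner == k]
      mine <- mine[spec$intensity[mine] > 0]
      if (!length(mine)) next
      best <- mine[order(-spec$intensity[mine],
                         abs(spec$mz[mine] - theo[k]))][1]
      intensity[k] <- spec$intensity[best]
      matched[k] <- spec$mz[best]
    }
  }
  structure(
    list(spectrum_id = spec$spectrum_id, intensity = intensity,
         matched_mz = matched),
    class = "reporter_vector"
  )
}

#' @export
print.reporter_vector <- function(x, ...) {
  cat("<reporter_vector '", x$spectrum_id, "'>\n", sep = "")
  print(rbind(intensity = x$intensity, matched_mz = x$matched_mz))
  invisible(x)
}

#' Read an isotopic impurity matrix from delimited text
#'
#' The file holds a square channel-by-channel matrix with header row and
#' first column giving channel labels; entry (i, j) is the fraction of
#' channel j's true signal observed in channel i.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return numeric matrix with channel dimnames.
#' @export
read_impurity_matrix <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE)
  m <- as.matrix(d)
  validate_impurity_matrix(m)
  m
}

#' Validate an impurity matrix
#'
#' @param m square numeric matrix; entries in \[0, 1\], column sums at most 1,
#'   diagonally dominant.
#' @return `m`, invisibly.
#' @export
validate_impurity_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("impurity matrix must be square")
  if (any(m < 0) || any(m > 1)) stop("impurity entries must lie in [0, 1]")
  if (any(colSums(m) > 1 + 1e-9)) stop("impurity column sums must be <= 1")
  if (any(diag(m) <= apply(m - diag(diag(m)), 2, max)))
    stop("impurity matrix must be diagonally dominant")
  invisible(m)
}

#' Apply isotopic impurity leakage (forward model)
#'
#' Computes observed = M %*% true. Used by the simulator and as the forward
#' half of the correction round-trip.
#'
#' @param intensity named numeric vector of true channel intensities
#'   (NA = missing, treated as 0).
#' @param impurities impurity matrix with matching channel order.
#' @return numeric vector of observed intensities.
#' @export
apply_impurities <- function(intensity, impurities) {
  x <- ifelse(is.na(intensity), 0, intensity)
  as.numeric(impurities %*% x)
}

#' Correct reporter intensities for isotopic impurities
#'
#' Solves observed = M \%*\% true for the true intensities under a
#' non-negativity constraint (non-negative least squares). Missing channels
#' are treated as zero during the solve and restored to missing afterwards.
#'
#' @param vec a `reporter_vector` from [extract_reporters()].
#' @param impurities square impurity matrix, channel order matching the
#'   vector.
#' @return corrected `reporter_vector`.
#' @export
correct_impurities <- function(vec, impurities) {
  n <- length(vec$intensity)
  if (!is.matrix(impurities) || nrow(impurities) != n || ncol(impurities) != n)
    stop("impurity matrix dimensions do not match the reporter vector")
  if (qr(impurities)$rank < n) stop("impurity matrix is singular")
  miss <- is.na(vec$intensity)
  if (all(impurities == diag(n))) return(vec)
  b <- ifelse(miss, 0, vec$intensity)
  sol <- pracma::lsqnonneg(impurities, b)$x
  sol[miss] <- NA_real_
  vec$intensity <- stats::setNames(sol, names(vec$intensity))
  vec
}

#' Interference-free index
#'
#' Per matrix row, IFI = 1 - mean(knockout-channel intensities) /
#' mean(parent-channel intensities), clamped to \[0, 1\]. In a knockout
#' standard, signal in a deleted protein's channel can only come from
#' co-isolated background, so IFI near 1 means interference-free
#' quantification. Missing values count as 0 in the means; rows whose parent
#' channels are all zero are reported as `NA`.
#'
#' @param mat a [quant_matrix()] (or plain matrix with channel columns)
#'   restricted to the rows of interest.
#' @param ko_channels,parent_channels disjoint, non-empty channel label sets.
#' @return numeric vector, one IFI in \[0, 1\] (or NA) per row.
#' @export
interference_free_index <- function(mat, ko_channels, parent_channels) {
  v <- if (inherits(mat, "quant_matrix")) mat$values else mat
  cols <- if (inherits(mat, "quant_matrix")) mat$cols$label else colnames(v)
  if (!length(ko_channels) || !length(parent_channels))
    stop("channel sets must be non-empty")
  if (length(intersect(ko_channels, parent_channels)))
    stop("channel sets must be disjoint")
  bad <- setdiff(c(ko_channels, parent_channels), cols)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  z <- v
  z[is.na(z)] <- 0
  ko <- rowMeans(z[, cols %in% ko_channels, drop = FALSE])
  pa <- rowMeans(z[, cols %in% parent_channels, drop = FALSE])
  ifi <- 1 - ko / pa
  ifi[pa == 0] <- NA_real_
  pmin(pmax(ifi, 0), 1)
}

#' Detect a diagnostic PTM ion in a spectrum
#'
#' Looks for the most intense peak within `tol_ppm` of `ion_mz`, requiring it
#' to sit strictly closer to the diagnostic mass than to `exclusion_mz`
#' (typically the 126 reporter, 0.0364 Th above the acetyl-lysine ion). The
#' tolerance window must not reach the exclusion mass; otherwise the two ions
#' cannot be told apart and an error asks for a smaller tolerance.
#'
#' @param spec a [spectrum()].
#' @param ion_mz diagnostic ion m/z (e.g. 126.0913 for acetyl-lysine).
#' @param tol_ppm positive tolerance in ppm.
#' @param exclusion_mz optional confounding mass to exclude.
#' @return list with `mz` and `intensity` of the matched peak, or `NULL`.
#' @export
detect_diagnostic_ion <- function(spec, ion_mz, tol_ppm = 50,
                                  exclusion_mz = NULL) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  w <- ion_mz * tol_ppm * 1e-6
  if (!is.null(exclusion_mz) && abs(exclusion_mz - ion_mz) <= w)
    stop("tolerance window includes the exclusion mass; ",
         "use a smaller tolerance")
  cand <- which(abs(spec$mz - ion_mz) <= w)
  if (!is.null(exclusion_mz) && length(cand))
    cand <- cand[abs(spec$mz[cand] - ion_mz) <
                   abs(spec$mz[cand] - exclusion_mz)]
  if (!length(cand)) return(NULL)
  best <- cand[order(-spec$intensity[cand], abs(spec$mz[cand] - ion_mz))][1]
  list(mz = spec$mz[best], intensity = spec$intensity[best])
}
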