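#' Define a dilution/spike design
#'
#' Maps channels to the relative concentration they carry in a standard,
#' e.g. a 4-order dilution series or the 1:5:10 two-proteome spike triplets.
#'
#' @param label channel labels.
#' @param concentration positive relative concentrations, one per channel.
#' @param replicate optional replicate tag per channel (e.g. triplet index).
#' @return data.frame of class `dilution_design`.
#' @export
dilution_design <- function(label, concentration, replicate = NA) {
  stopifnot(length(label) == length(concentration))
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (length(unique(concentration)) < 2)
    stop("design needs at least two distinct concentrations")
  d <- data.frame(label = as.character(label),
                  concentration = as.numeric(concentration),
                  replicate = rep_len(replicate, length(label)),
                  stringsAsFactors = FALSE)
  class(d) <- c("dilution_design", "data.frame")
  d
}

# channel columns of mat matching the design, in design order
.design_cols <- function(mat, design) {
  idx <- match(design$label, mat$cols$label)
  if (anyNA(idx))
    stop("design channels missing from matrix: ",
         paste(design$label[is.na(idx)], collapse = ", "))
  idx
}

#' Dilution linearity diagnostic
#'
#' Regresses the mean log10 reporter intensity of each channel (missing
#' values excluded from the means) on log10 relative concentration and
#' returns the fit's R-squared and slope — the intrascan linear dynamic
#' range check. A slope of 1 with R-squared near 1 indicates proportional
#' response across the series.
#'
#' @param mat a [quant_matrix()].
#' @param design a [dilution_design()] with at least 3 distinct levels.
#' @return list with `r_squared`, `slope`, and `channel_means` (data.frame
#'   of label, concentration, mean log10 intensity).
#' @export
linearity <- function(mat, design) {
  if (length(unique(design$concentration)) < 3)
    stop("linearity needs at least 3 concentration levels")
  idx <- .design_cols(mat, design)
  mean_log10 <- vapply(idx, function(j) {
    x <- mat$values[, j]
    mean(log10(x[!is.na(x) & x > 0]))
  }, numeric(1))
  fit <- stats::lm(mean_log10 ~ log10(design$concentration))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_log10 - mean(mean_log10))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  list(
    r_squared = r2,
    slope = unname(stats::coef(fit)[2]),
    channel_means = data.frame(label = design$label,
                               concentration = design$concentration,
                               mean_log10 = mean_log10,
                               stringsAsFactors = FALSE)
  )
}

#' Missing-value profile across a dilution design
#'
#' Per channel, the fraction of features with missing values, paired with
#' the design concentration — the diagnostic behind missing-reporter trends
#' as channel load falls.
#'
#' @param mat a [quant_matrix()].
#' @param design a [dilution_design()].
#' @return data.frame `label`, `concentration`, `missing_fraction`.
#' @export
missing_profile <- function(mat, design) {
  idx <- .design_cols(mat, design)
  frac <- vapply(idx, function(j) mean(is.na(mat$values[, j])), numeric(1))
  data.frame(label = design$label, concentration = design$concentration,
             missing_fraction = frac, stringsAsFactors = FALSE)
}

#' Spike-in ratio accuracy
#'
#' For each spiked feature, the mean intensity at each design concentration
#' level is normalized to the lowest level; the aggregate observed ratio per
#' level is the median (default) or mean across features. For a 1:5:10
#' two-proteome standard the ideal return is (1, 5, 10); counting noise
#' compresses the upper levels toward 1.
#'
#' @param mat a [quant_matrix()].
#' @param design a [dilution_design()]; channels sharing a concentration are
#'   replicate channels of that level.
#' @param spike_features feature ids of the spiked proteome.
#' @param aggregate `"median"` (default) or `"mean"` across features.
#' @return list with `observed` (named by level, lowest = 1), `expected`,
#'   and `per_feature` matrix (features x levels).
#' @export
ratio_accuracy <- function(mat, design, spike_features,
                           aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  idx <- .design_cols(mat, design)
  missing_f <- setdiff(spike_features, rownames(mat$values))
  if (length(missing_f) == length(spike_features))
    stop("no spike features present in the matrix")
  feats <- intersect(spike_features, rownames(mat$values))
  levels <- sort(unique(design$concentration))
  per <- matrix(NA_real_, length(feats), length(levels),
                dimnames = list(feats, as.character(levels)))
  for (k in seq_along(levels)) {
    cols <- idx[design$concentration == levels[k]]
    per[, k] <- rowMeans(mat$values[feats, cols, drop = FALSE], na.rm = TRUE)
  }
  per <- per / per[, 1]
  agg <- apply(per, 2, function(x)
    if (aggregate == "median") stats::median(x, na.rm = TRUE)
    else mean(x, na.rm = TRUE))
  list(observed = agg, expected = levels / levels[1], per_feature = per)
}

#' Carrier-effect curve
#'
#' For a series of runs acquired with increasing carrier load, returns the
#' observed ratio between two channels holding a known design ratio at each
#' carrier level — flat at the known ratio when quantification is
#' carrier-independent, compressing toward 1 when carrier-dominated ion
#' sampling or co-isolation erodes it.
#'
#' @param matrices list of [quant_matrix()], one per carrier level.
#' @param carrier_levels positive numeric vector, same length.
#' @param num_channel,den_channel labels of the compared channels (numerator
#'   holds `known_ratio` times the denominator by design).
#' @param known_ratio the designed ratio (default 5).
#' @param features optional feature subset carrying the known ratio.
#' @return data.frame `carrier_level`, `observed_ratio` (median across
#'   features), `known_ratio`.
#' @export
carrier_curve <- function(matrices, carrier_levels, num_channel,
                          den_channel, known_ratio = 5, features = NULL) {
  if (length(matrices) != length(carrier_levels))
    stop("one matrix per carrier level required")
  obs <- vapply(matrices, function(m) {
    ia <- which(m$cols$label == num_channel)
    ib <- which(m$cols$label == den_channel)
    if (!length(ia) || !length(ib))
      stop("compared channels missing from a matrix")
    v <- m$values
    if (!is.null(features))
      v <- v[intersect(features, rownames(v)), , drop = FALSE]
    r <- rowMeans(v[, ia, drop = FALSE], na.rm = TRUE) /
      rowMeans(v[, ib, drop = FALSE], na.rm = TRUE)
    stats::median(r[is.finite(r)], na.rm = TRUE)
  }, numeric(1))
  data.frame(carrier_level = carrier_levels, observed_ratio = obs,
             known_ratio = known_ratio)
}
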