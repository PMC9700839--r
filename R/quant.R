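#' Construct a feature-by-channel quantification matrix
#'
#' Thin container pairing a numeric value matrix (features in rows) with
#' per-column metadata (run, channel label, role). Missing measurements are
#' `NA`; negative values are rejected.
#'
#' @param values numeric matrix, rownames = feature ids.
#' @param cols data.frame with one row per matrix column: `run_id`, `label`,
#'   `role`, optionally `expected_amount` / `condition`.
#' @return object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, cols) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  if (nrow(cols) != ncol(values))
    stop("cols must have one row per matrix column")
  if (is.null(rownames(values))) stop("values needs feature rownames")
  colnames(values) <- paste(cols$run_id, cols$label, sep = ".")
  structure(list(values = values, cols = cols), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %d features x %d channels (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$cols$role), collapse = "/")))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Assemble a quantification matrix from reporter vectors
#'
#' Sums per-channel reporter intensities over all spectra identified to the
#' same feature (peptide, protein or PTM site), then drops features whose
#' mean reporter intensity across channels falls below
#' `min_avg_intensity` — the minimum average reporter intensity filter
#' (default 10). Spectra absent from the identification table are ignored.
#'
#' @param vectors list of `reporter_vector` objects.
#' @param id_table data.frame with columns `spectrum_id`, `feature_id`;
#'   duplicate (spectrum, feature) pairs are an error.
#' @param design the [plex_design()] the vectors were extracted with.
#' @param min_avg_intensity non-negative threshold on the feature's mean
#'   across non-missing channels (default 10).
#' @param run_id run identifier stored in the column metadata.
#' @return a [quant_matrix()].
#' @export
assemble <- function(vectors, id_table, design, min_avg_intensity = 10,
                     run_id = "run") {
  stopifnot(all(c("spectrum_id", "feature_id") %in% names(id_table)))
  if (anyDuplicated(id_table[c("spectrum_id", "feature_id")]))
    stop("duplicate (spectrum, feature) pairs in identification table")
  ids <- vapply(vectors, `[[`, "", "spectrum_id")
  hit <- match(ids, id_table$spectrum_id)
  keep <- which(!is.na(hit))
  features <- sort(unique(id_table$feature_id[hit[keep]]))
  values <- matrix(NA_real_, length(features), nrow(design),
                   dimnames = list(features, design$label))
  for (i in keep) {
    f <- id_table$feature_id[hit[i]]
    v <- vectors[[i]]$intensity[design$label]
    ok <- !is.na(v)
    row <- values[f, ]
    row[ok] <- ifelse(is.na(row[ok]), 0, row[ok]) + v[ok]
    values[f, ] <- row
  }
  if (min_avg_intensity > 0 && nrow(values)) {
    m <- rowMeans(values, na.rm = TRUE)
    m[is.nan(m)] <- 0
    values <- values[m >= min_avg_intensity, , drop = FALSE]
  }
  quant_matrix(values, data.frame(run_id = run_id, label = design$label,
                                  role = design$role,
                                  expected_amount = design$expected_amount,
                                  stringsAsFactors = FALSE))
}

#' Remove channels from a quantification matrix
#'
#' Drops the named channels (e.g. a carrier-adjacent channel suffering
#' impurity-driven ratio distortion) and any feature row left all-missing.
#'
#' @param mat a [quant_matrix()].
#' @param labels channel labels to exclude; empty set is the identity.
#' @return a [quant_matrix()].
#' @export
exclude_channels <- function(mat, labels) {
  if (!length(labels)) return(mat)
  bad <- setdiff(labels, mat$cols$label)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  keep <- !(mat$cols$label %in% labels)
  values <- mat$values[, keep, drop = FALSE]
  nonempty <- rowSums(!is.na(values)) > 0
  quant_matrix(values[nonempty, , drop = FALSE],
               mat$cols[keep, , drop = FALSE])
}

#' Total-sum normalization of channel columns
#'
#' Scales each selected column so its (missing-ignored) sum equals the mean
#' of the pre-scaling column sums — the total sum-based normalization used
#' before final single-cell analysis. Zero-sum columns cannot be scaled;
#' they are left untouched and flagged in the `"unscaled"` attribute.
#'
#' @param mat a [quant_matrix()].
#' @param roles roles of columns to normalize (default `"single_cell"`).
#' @return a normalized [quant_matrix()] with attribute `"unscaled"` naming
#'   any zero-sum columns.
#' @export
total_sum_normalize <- function(mat, roles = "single_cell") {
  sel <- which(mat$cols$role %in% roles)
  if (!length(sel)) stop("no columns with role(s): ",
                         paste(roles, collapse = ", "))
  sums <- colSums(mat$values[, sel, drop = FALSE], na.rm = TRUE)
  target <- mean(sums)
  zero <- sums == 0
  scale <- ifelse(zero, 1, target / sums)
  mat$values[, sel] <- sweep(mat$values[, sel, drop = FALSE], 2, scale, "*")
  attr(mat, "unscaled") <- mat$cols$label[sel][zero]
  mat
}

#' Capped treatment/control ratio table
#'
#' In `peptide_pairwise` mode (the default rollup used for bulk protein
#' ratios), each feature's ratio is the median over all pairwise a/b column
#' ratios of its peptides, with a two-sided t-test on the log2 pairwise
#' ratios against 0 supplying the p-value; an optional `feature_map` rolls
#' peptide rows up to parent features. In `feature_mean` mode the ratio is
#' mean(group a) / mean(group b) per row. Ratios are clamped to
#' `[1/cap, cap]`; a feature detected only in group a is reported at `cap`
#' (only in group b: at `1/cap`); features missing in both groups are
#' omitted.
#'
#' @param mat a [quant_matrix()].
#' @param group_a,group_b disjoint, non-empty sets of column indices or
#'   column names (`run_id.label`).
#' @param cap ratio cap (default 100, the tooling maximum).
#' @param level `"peptide_pairwise"` or `"feature_mean"`.
#' @param feature_map optional data.frame `peptide_id`, `feature_id` for
#'   peptide-to-protein rollup in pairwise mode.
#' @return data.frame of class `ratio_table`: `feature_id`, `ratio`,
#'   `p_value`, `n_obs`.
#' @export
compute_ratios <- function(mat, group_a, group_b, cap = 100,
                           level = c("peptide_pairwise", "feature_mean"),
                           feature_map = NULL) {
  level <- match.arg(level)
  if (cap <= 1) stop("cap must exceed 1")
  cn <- colnames(mat$values)
  resolve <- function(g) if (is.numeric(g)) as.integer(g) else match(g, cn)
  ia <- resolve(group_a); ib <- resolve(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown group columns")
  if (!length(ia) || !length(ib)) stop("groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  v <- mat$values
  rows <- rownames(v)
  parents <- if (is.null(feature_map)) rows else
    feature_map$feature_id[match(rows, feature_map$peptide_id)]
  out <- list()
  for (f in unique(parents[!is.na(parents)])) {
    sub <- v[which(parents == f), , drop = FALSE]
    a <- sub[, ia, drop = FALSE]; b <- sub[, ib, drop = FALSE]
    if (all(is.na(a)) && all(is.na(b))) next
    if (all(is.na(a))) {
      out[[f]] <- data.frame(feature_id = f, ratio = 1 / cap,
                             p_value = NA_real_, n_obs = 0L)
      next
    }
    if (all(is.na(b))) {
      out[[f]] <- data.frame(feature_id = f, ratio = cap,
                             p_value = NA_real_, n_obs = 0L)
      next
    }
    if (level == "feature_mean") {
      r <- mean(a, na.rm = TRUE) / mean(b, na.rm = TRUE)
      ratios <- r
    } else {
      # all pairwise a/b ratios, per peptide row
      ratios <- unlist(lapply(seq_len(nrow(sub)), function(i) {
        as.numeric(outer(a[i, ], b[i, ], "/"))
      }))
      ratios <- ratios[is.finite(ratios) & ratios > 0]
      if (!length(ratios)) next
      r <- stats::median(ratios)
    }
    p <- if (length(ratios) >= 2 && stats::sd(log2(ratios)) > 0)
      stats::t.test(log2(ratios), mu = 0)$p.value else NA_real_
    out[[f]] <- data.frame(feature_id = f,
                           ratio = min(max(r, 1 / cap), cap),
                           p_value = p, n_obs = length(ratios))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(0), ratio = numeric(0),
               p_value = numeric(0), n_obs = integer(0))
  rownames(res) <- NULL
  class(res) <- c("ratio_table", "data.frame")
  attr(res, "cap") <- cap
  res
}

#' Normalize PTM-site ratios to their parent protein ratio
#'
#' Divides each modified-peptide (PTM) ratio by the ratio of the protein it
#' maps to, so that a change in site occupancy is separated from a change in
#' total protein abundance; the cap is re-applied after division. PTMs with
#' no mapped protein ratio are omitted with a warning. Upstream, parent
#' ratios should come from proteins with more than one unique unmodified
#' peptide.
#'
#' @param ptm_ratios,protein_ratios `ratio_table`s from [compute_ratios()].
#' @param mapping data.frame with columns `ptm_id`, `protein_id`.
#' @param cap ratio cap (defaults to the PTM table's cap attribute, else
#'   100).
#' @return `ratio_table` of normalized PTM ratios.
#' @export
normalize_ptm_to_protein <- function(ptm_ratios, protein_ratios, mapping,
                                     cap = NULL) {
  if (is.null(cap)) cap <- attr(ptm_ratios, "cap")
  if (is.null(cap)) cap <- 100
  prot <- mapping$protein_id[match(ptm_ratios$feature_id, mapping$ptm_id)]
  pr <- protein_ratios$ratio[match(prot, protein_ratios$feature_id)]
  drop <- is.na(pr)
  if (any(drop))
    warning(sum(drop), " PTM feature(s) without a mapped protein ratio ",
            "omitted")
  res <- ptm_ratios[!drop, , drop = FALSE]
  res$ratio <- pmin(pmax(res$ratio / pr[!drop], 1 / cap), cap)
  res$p_value <- NA_real_
  rownames(res) <- NULL
  attr(res, "cap") <- cap
  res
}

#' Export a matrix in long (3-D) form
#'
#' One row per (feature, single-cell column): cell index, condition and
#' abundance, plus a log10-scaled abundance column — the layout consumed by
#' 3-D matrix viewers for per-cell expression display. Missing abundances
#' are emitted as NA rows.
#'
#' @param mat a [quant_matrix()].
#' @param conditions character vector, one condition per single-cell column
#'   (or a named vector keyed by column name).
#' @return data.frame `feature_id`, `cell_index`, `condition`, `abundance`,
#'   `log10_abundance`.
#' @export
export_3d <- function(mat, conditions) {
  sel <- which(mat$cols$role == "single_cell")
  if (!length(sel)) stop("matrix has no single-cell columns")
  cn <- colnames(mat$values)[sel]
  cond <- if (!is.null(names(conditions))) {
    if (!all(cn %in% names(conditions)))
      stop("every single-cell column needs a condition")
    unname(conditions[cn])
  } else rep_len(conditions, length(sel))
  v <- mat$values[, sel, drop = FALSE]
  out <- data.frame(
    feature_id = rep(rownames(v), times = ncol(v)),
    cell_index = rep(seq_along(sel), each = nrow(v)),
    condition = rep(cond, each = nrow(v)),
    abundance = as.numeric(v),
    stringsAsFactors = FALSE
  )
  out$log10_abundance <- log10(out$abundance)
  out
}
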