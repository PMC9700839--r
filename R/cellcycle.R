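#' Construct a cell-cycle marker panel
#'
#' Maps marker proteins to the cell-cycle stage they flag (G1, S, G2M,
#' prophase, prometaphase, ...). Panels are the guidance used to estimate
#' per-cell cycle status from single-cell protein abundances.
#'
#' @param protein character vector of protein ids.
#' @param stage character vector of stage labels, same length.
#' @param name panel name.
#' @return data.frame of class `marker_panel` with columns `protein`,
#'   `stage`.
#' @export
marker_panel <- function(protein, stage, name = "panel") {
  stopifnot(length(protein) == length(stage))
  if (!length(protein)) stop("panel is empty")
  if (anyDuplicated(protein))
    stop("each protein must map to exactly one stage")
  if (length(unique(stage)) < 2) stop("panel needs at least two stages")
  p <- data.frame(protein = as.character(protein),
                  stage = as.character(stage), stringsAsFactors = FALSE)
  attr(p, "name") <- name
  class(p) <- c("marker_panel", "data.frame")
  p
}

#' Read a marker panel from 2-column delimited text
#'
#' @param path file with columns `protein`, `stage` (header required).
#' @param sep field separator (default tab).
#' @return a [marker_panel()].
#' @export
read_marker_panel <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("protein", "stage") %in% names(d)))
    stop("panel file needs 'protein' and 'stage' columns")
  marker_panel(d$protein, d$stage, name = basename(path))
}

#' Built-in synthetic cell-cycle marker panel
#'
#' A small stand-in panel (synthetic marker ids, five stages) shipped for
#' tests and examples; users analysing real data should supply a curated
#' panel such as a published 119-protein marker set as delimited text.
#'
#' @param markers_per_stage markers generated per stage (default 8).
#' @return a [marker_panel()].
#' @export
synthetic_panel <- function(markers_per_stage = 8) {
  stages <- c("G1", "S", "G2M", "prophase", "prometaphase")
  marker_panel(
    protein = paste0("MK_", rep(stages, each = markers_per_stage), "_",
                     seq_len(markers_per_stage)),
    stage = rep(stages, each = markers_per_stage),
    name = "synthetic_cellcycle_panel"
  )
}

#' Score per-cell cell-cycle stage from a marker panel
#'
#' Estimator: single-cell columns are first brought to equal total signal
#' (so scores are invariant to per-cell global intensity scaling), each
#' marker row is min-max scaled across cells, and a cell's score for a stage
#' is the mean scaled abundance of that stage's detected markers. A stage is
#' scored only when at least `min_markers` of its panel proteins are present
#' in the matrix. The assigned stage is the argmax; the margin is the gap to
#' the runner-up. Cells with no scored stage are flagged unassigned.
#'
#' @param mat a [quant_matrix()] with single-cell columns; rownames are
#'   protein ids matching the panel.
#' @param panel a [marker_panel()].
#' @param min_markers minimum detected markers per stage (default 3).
#' @return object of class `stage_scores`: data.frame with one row per cell
#'   (`cell`, one score column per scored stage, `stage`, `margin`).
#' @export
score_cells <- function(mat, panel, min_markers = 3) {
  stopifnot(inherits(panel, "marker_panel"))
  sel <- which(mat$cols$role == "single_cell")
  if (!length(sel)) stop("matrix has no single-cell columns")
  v <- mat$values[, sel, drop = FALSE]
  # per-cell total normalization, then row min-max scaling
  cs <- colSums(v, na.rm = TRUE)
  cs[cs == 0] <- 1
  v <- sweep(v, 2, mean(cs) / cs, "*")
  rng <- t(apply(v, 1, function(r) range(r, na.rm = TRUE)))
  span <- rng[, 2] - rng[, 1]
  span[!is.finite(span) | span == 0] <- 1
  scaled <- (v - rng[, 1]) / span
  stages <- unique(panel$stage)
  score <- matrix(NA_real_, ncol(v), length(stages),
                  dimnames = list(colnames(v), stages))
  for (st in stages) {
    markers <- intersect(panel$protein[panel$stage == st], rownames(v))
    if (length(markers) < min_markers) next
    score[, st] <- colMeans(scaled[markers, , drop = FALSE], na.rm = TRUE)
  }
  scored <- colSums(!is.na(score)) > 0
  score <- score[, scored, drop = FALSE]
  if (!ncol(score)) {
    res <- data.frame(cell = colnames(v), stage = NA_character_,
                      margin = NA_real_, stringsAsFactors = FALSE)
    class(res) <- c("stage_scores", "data.frame")
    return(res)
  }
  assign_one <- function(s) {
    if (!length(s) || all(is.na(s))) return(c(NA_character_, NA_real_))
    o <- order(s, decreasing = TRUE, na.last = TRUE)
    top <- o[1]
    margin <- if (sum(!is.na(s)) >= 2) s[top] - s[o[2]] else 0
    c(colnames(score)[top], margin)
  }
  ass <- t(apply(score, 1, assign_one))
  res <- data.frame(cell = rownames(score), score,
                    stage = ass[, 1], margin = as.numeric(ass[, 2]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(res) <- NULL
  class(res) <- c("stage_scores", "data.frame")
  res
}

#' Stage composition per condition
#'
#' Tabulates the fraction of assigned cells in each stage within each
#' condition and, for two conditions, the stage-wise fraction ratio
#' (first/second) — e.g. a 4-fold prophase enrichment under drug treatment.
#'
#' @param scores a `stage_scores` from [score_cells()].
#' @param groups condition per cell: named by cell id, or positional.
#' @return list with `fractions` (stage x condition matrix) and `ratios`
#'   (named vector, NULL unless exactly two conditions).
#' @export
stage_composition <- function(scores, groups) {
  g <- if (!is.null(names(groups))) {
    if (!all(scores$cell %in% names(groups)))
      stop("every cell needs a condition")
    unname(groups[scores$cell])
  } else rep_len(groups, nrow(scores))
  ok <- !is.na(scores$stage)
  tab <- table(stage = scores$stage[ok], condition = g[ok])
  frac <- prop.table(tab, margin = 2)
  fractions <- matrix(as.numeric(frac), nrow(frac), ncol(frac),
                      dimnames = dimnames(frac))
  ratios <- NULL
  if (ncol(fractions) == 2) {
    ratios <- fractions[, 1] / fractions[, 2]
    names(ratios) <- rownames(fractions)
  }
  list(fractions = fractions, ratios = ratios)
}
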