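# deterministic polynomial rolling hash of a config, for provenance headers
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(cfg_hash) {
  sprintf("# scpriq %s; config_hash=%s",
          as.character(utils::packageVersion("scpriq")), cfg_hash)
}

.write_table <- function(d, path, header) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic-to-diagnostics pipeline
#'
#' Chains the processing stages in fixed order — simulate (or read an
#' existing MGF), calibrate, reporter-presence filter, extract, assemble,
#' normalize, score cell cycle (when a panel is given), evaluate linearity —
#' writing each stage's output as delimited text / MGF with a provenance
#' header, and returns a manifest of artifacts. Any stage error is
#' propagated with the stage name.
#'
#' @param config path to a YAML file or an equivalent named list. Recognized
#'   keys: `out_dir` (required), `seed`, `n_spectra`, `mgf` (input MGF path;
#'   when absent a run is simulated), `design` (path to a design table,
#'   default the packaged two-proteome standard), `tol_da` (0.005),
#'   `search_tol_ppm` (50), `blank_factor` (3), `min_avg_intensity` (10),
#'   `panel` (marker panel path, optional), `calibrate` (TRUE).
#' @return list with `manifest` (data.frame stage/path) and `results`
#'   (in-memory stage outputs), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config: 'out_dir' is required")
  hash <- .config_hash(cfg)
  hdr <- .provenance(hash)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(key, default) as.numeric(
    if (is.null(cfg[[key]])) default else cfg[[key]])
  manifest <- data.frame(stage = character(0), path = character(0),
                         stringsAsFactors = FALSE)
  add <- function(stage, path) manifest[nrow(manifest) + 1L, ] <<-
    c(stage, path)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))

  design <- stage("design", {
    if (!is.null(cfg$design)) {
      if (!file.exists(cfg$design)) stop("no such file: ", cfg$design)
      read_plex_design(cfg$design)
    } else design_two_proteome()
  })

  sim_truth <- NULL
  spectra <- stage("input", {
    if (!is.null(cfg$mgf)) {
      if (!file.exists(cfg$mgf)) stop("no such file: ", cfg$mgf)
      read_mgf(cfg$mgf)
    } else {
      res <- simulate_run(sim_params(
        n_spectra = num("n_spectra", 500), design = design,
        offset_ppm = num("offset_ppm", 0), seed = num("seed", 1)))
      sim_truth <- res$truth
      p <- file.path(cfg$out_dir, "simulated.mgf")
      write_mgf(res$spectra, p)
      add("simulate", p)
      tp <- file.path(cfg$out_dir, "sim_truth.tsv")
      .write_table(res$truth$spectra, tp, hdr)
      add("simulate", tp)
      res$spectra
    }
  })

  model <- NULL
  if (!identical(cfg$calibrate, FALSE)) {
    spectra <- stage("calibrate", {
      cal <- calibrate_run(spectra, design,
                           search_tol_ppm = num("search_tol_ppm", 50))
      model <- cal$model
      p <- file.path(cfg$out_dir, "calibration.tsv")
      .write_table(data.frame(offset_ppm = cal$model$offset_ppm,
                              range_low = cal$model$mass_range[1],
                              range_high = cal$model$mass_range[2],
                              n_anchors = cal$model$n_anchors), p, hdr)
      add("calibrate", p)
      cal$spectra
    })
  }

  filt <- stage("filter", {
    required <- design$label[design$role %in% c("single_cell", "standard")]
    res <- filter_by_reporter_presence(
      spectra, design, required_channels = required,
      tol_da = num("tol_da", 0.005),
      out_path = file.path(cfg$out_dir, "run.mgf"))
    add("filter", file.path(cfg$out_dir, "Filteredrun.mgf"))
    p <- file.path(cfg$out_dir, "qc_summary.tsv")
    flagged <- flag_failed_runs(list(res$summary),
                                blank_channel = design$label[1],
                                factor = num("blank_factor", 3))
    .write_table(qc_summary_table(flagged), p, hdr)
    add("filter", p)
    res
  })

  vectors <- stage("extract", lapply(filt$spectra, extract_reporters,
                                     design = design,
                                     tol_value = num("tol_da", 0.005)))

  mat <- stage("assemble", {
    id_table <- if (!is.null(sim_truth)) sim_truth$spectra else
      data.frame(
        spectrum_id = vapply(vectors, `[[`, "", "spectrum_id"),
        feature_id = vapply(vectors, `[[`, "", "spectrum_id"),
        stringsAsFactors = FALSE)
    m <- assemble(vectors, id_table, design,
                  min_avg_intensity = num("min_avg_intensity", 10))
    p <- file.path(cfg$out_dir, "quant_matrix.tsv")
    .write_table(data.frame(feature_id = rownames(m$values), m$values,
                            check.names = FALSE), p, hdr)
    add("assemble", p)
    m
  })

  norm <- stage("normalize", {
    roles <- intersect(c("single_cell", "standard"), mat$cols$role)
    m <- total_sum_normalize(mat, roles = roles)
    p <- file.path(cfg$out_dir, "quant_matrix_normalized.tsv")
    .write_table(data.frame(feature_id = rownames(m$values), m$values,
                            check.names = FALSE), p, hdr)
    add("normalize", p)
    m
  })

  scores <- NULL
  if (!is.null(cfg$panel)) scores <- stage("cellcycle", {
    panel <- read_marker_panel(cfg$panel)
    s <- score_cells(norm, panel)
    p <- file.path(cfg$out_dir, "stage_scores.tsv")
    .write_table(s, p, hdr)
    add("cellcycle", p)
    s
  })

  evalres <- stage("evaluate", {
    # linearity must be read off the raw assembled matrix: total-sum
    # normalization equalizes column sums and erases the dilution signal
    conc <- mat$cols$expected_amount
    ok <- !is.na(conc) & conc > 0
    if (sum(ok) >= 3 && length(unique(conc[ok])) >= 3) {
      dd <- dilution_design(mat$cols$label[ok], conc[ok])
      lin <- linearity(mat, dd)
      mp <- missing_profile(mat, dd)
      p <- file.path(cfg$out_dir, "linearity.tsv")
      .write_table(data.frame(r_squared = lin$r_squared,
                              slope = lin$slope), p, hdr)
      add("evaluate", p)
      p2 <- file.path(cfg$out_dir, "missing_profile.tsv")
      .write_table(mp, p2, hdr)
      add("evaluate", p2)
      lin
    } else NULL
  })

  invisible(list(manifest = manifest,
                 results = list(design = design, calibration = model,
                                qc = filt$summary, matrix = norm,
                                scores = scores, linearity = evalres)))
}
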