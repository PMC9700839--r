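#' Standard plex designs
#'
#' `design_two_proteome()` is the 9-plex two-proteome accuracy standard:
#' constant human background in every channel with a bacterial spike in a
#' 1:5:10 dilution series repeated in three channel triplets.
#' `design_single_cell()` is the single-cell layout: a 126 method blank,
#' single-cell wells 127N-133N and a 134N carrier.
#'
#' @return a [plex_design()].
#' @export
design_two_proteome <- function() {
  plex_design(
    labels = c("126", "127N", "128N", "129N", "130N", "131N", "132N",
               "133N", "134N"),
    roles = "standard",
    expected_amount = rep(c(1, 5, 10), 3),
    plex = "TMTPro"
  )
}

#' @rdname design_two_proteome
#' @param carrier_level relative carrier concentration (default 250, a
#'   typical single-cell carrier load).
#' @export
design_single_cell <- function(carrier_level = 250) {
  plex_design(
    labels = c("126", "127N", "128N", "129N", "130N", "131N", "132N",
               "133N", "134N"),
    roles = c("blank", rep("single_cell", 7), "carrier"),
    expected_amount = c(0, rep(1, 7), carrier_level),
    plex = "TMTPro"
  )
}

#' Simulation parameters for TIMSTOF-like MS2 spectra
#'
#' Defines the generative model: per-channel reporter intensities follow a
#' Poisson counting model around the design's relative abundances, reporter
#' m/z carries a Gaussian ppm error plus an optional systematic offset,
#' isotopic impurities leak between channels before counting noise, and
#' spectra also carry backbone fragment peaks, uniform noise peaks and
#' (optionally) the 126.0913 acetyl-lysine diagnostic ion. Setting a finite
#' `ion_budget` makes all channels share a fixed ion-sampling depth (so a
#' large carrier starves the single-cell channels); `interference_fraction`
#' adds co-isolated background proportional to the total ion current equally
#' to every channel. With both at their defaults (off) the generator is
#' linear in the design abundances.
#'
#' @param n_spectra number of MS2 spectra.
#' @param design a [plex_design()]; channel relative abundances default to
#'   `expected_amount` (blank channels 0).
#' @param relative_abundance optional named per-channel override.
#' @param mean_ions Poisson mean of the most abundant non-carrier channel
#'   (default 1e4, a high-signal bench regime).
#' @param ppm_sigma Gaussian mass-error s.d. in ppm (default 4).
#' @param offset_ppm systematic mass offset in ppm (default 0).
#' @param n_noise_peaks uniform noise peaks per spectrum (default 30).
#' @param n_backbone_peaks backbone fragment peaks per spectrum (default 20).
#' @param impurities optional impurity matrix (channel order = design).
#' @param channel_prob per-channel occupancy probability (default 1 where
#'   abundance > 0).
#' @param diagnostic_ion_fraction fraction of spectra carrying the
#'   acetyl-lysine diagnostic ion (default 0).
#' @param interference_fraction co-isolation leak per channel as a fraction
#'   of total reporter ion current (default 0).
#' @param ion_budget total reporter ion-sampling budget per spectrum
#'   (default `Inf` = unconstrained).
#' @param n_features number of distinct peptide features spectra are drawn
#'   from.
#' @param seed RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_spectra = 1000,
                       design = design_two_proteome(),
                       relative_abundance = NULL,
                       mean_ions = 1e4,
                       ppm_sigma = 4,
                       offset_ppm = 0,
                       n_noise_peaks = 30,
                       n_backbone_peaks = 20,
                       impurities = NULL,
                       channel_prob = NULL,
                       diagnostic_ion_fraction = 0,
                       interference_fraction = 0,
                       ion_budget = Inf,
                       n_features = max(1L, n_spectra %/% 5L),
                       seed = 1L) {
  if (is.null(relative_abundance)) {
    relative_abundance <- ifelse(is.na(design$expected_amount),
                                 ifelse(design$role == "blank", 0, 1),
                                 design$expected_amount)
    relative_abundance[design$role == "blank"] <- 0
    names(relative_abundance) <- design$label
  } else {
    relative_abundance <- relative_abundance[design$label]
  }
  if (is.null(channel_prob)) {
    channel_prob <- as.numeric(relative_abundance > 0)
    names(channel_prob) <- design$label
  } else {
    channel_prob <- channel_prob[design$label]
  }
  p <- list(
    n_spectra = as.integer(n_spectra), design = design,
    relative_abundance = relative_abundance, mean_ions = mean_ions,
    ppm_sigma = ppm_sigma, offset_ppm = offset_ppm,
    n_noise_peaks = as.integer(n_noise_peaks),
    n_backbone_peaks = as.integer(n_backbone_peaks),
    impurities = impurities, channel_prob = channel_prob,
    diagnostic_ion_fraction = diagnostic_ion_fraction,
    interference_fraction = interference_fraction,
    ion_budget = ion_budget, n_features = as.integer(n_features),
    seed = as.integer(seed)
  )
  stopifnot(p$n_spectra >= 0, p$mean_ions > 0, p$ppm_sigma >= 0,
            p$n_noise_peaks >= 0, p$n_backbone_peaks >= 0,
            p$diagnostic_ion_fraction >= 0, p$diagnostic_ion_fraction <= 1,
            p$interference_fraction >= 0, p$ion_budget > 0,
            p$n_features >= 1, all(p$relative_abundance >= 0),
            all(p$channel_prob >= 0 & p$channel_prob <= 1))
  if (!is.null(impurities)) validate_impurity_matrix(impurities)
  class(p) <- "sim_params"
  p
}

# noise/backbone m/z avoid the reporter region so extraction ground truth
# stays exact; real spectra are also sparse there after binning
.rand_fragment_mz <- function(n, lo = 140, hi = 1700) {
  stats::runif(n, lo, hi)
}

#' Simulate a run of TIMSTOF-like MS2 spectra
#'
#' Draws `n_spectra` spectra under the model of [sim_params()] and returns
#' them with full ground truth: per-spectrum feature id, the pre-noise true
#' channel intensities, the channel occupancy actually emitted (a Poisson
#' draw of zero emits no peak), and the injected mass offset. Deterministic
#' given the seed.
#'
#' @param params a [sim_params()].
#' @return list with `spectra` (list of [spectrum()]) and `truth` (list:
#'   `spectra` data.frame with spectrum_id/feature_id, `occupancy` and
#'   `true_intensity` matrices, `offset_ppm`).
#' @export
simulate_run <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  d <- params$design
  nch <- nrow(d)
  theo <- d$mz
  rel <- params$relative_abundance
  diag_mz <- diagnostic_ions()$mz[1]
  n <- params$n_spectra
  spectra <- vector("list", n)
  occupancy <- matrix(FALSE, n, nch, dimnames = list(NULL, d$label))
  true_int <- matrix(0, n, nch, dimnames = list(NULL, d$label))
  feature <- sprintf("PEP_%05d", sample.int(params$n_features, n,
                                            replace = TRUE))
  ids <- sprintf("sim.%05d", seq_len(n))
  top <- max(rel[d$role != "carrier"], 1e-12)
  for (i in seq_len(n)) {
    pep_factor <- stats::rlnorm(1, 0, 0.5)
    occ <- stats::runif(nch) < params$channel_prob
    lambda <- rel / top * params$mean_ions * pep_factor * occ
    if (params$interference_fraction > 0)
      lambda <- lambda + params$interference_fraction * sum(lambda)
    if (is.finite(params$ion_budget) && sum(lambda) > params$ion_budget)
      lambda <- lambda * params$ion_budget / sum(lambda)
    occupancy[i, ] <- occ
    true_int[i, ] <- lambda
    if (!is.null(params$impurities))
      lambda <- as.numeric(params$impurities %*% lambda)
    counts <- stats::rpois(nch, lambda)
    emit <- counts > 0
    rep_mz <- theo[emit] *
      (1 + (params$offset_ppm +
              stats::rnorm(sum(emit), 0, params$ppm_sigma)) * 1e-6)
    rep_int <- counts[emit]
    occupancy[i, ] <- occupancy[i, ] & (counts > 0)
    extra_mz <- numeric(0); extra_int <- numeric(0)
    if (params$diagnostic_ion_fraction > 0 &&
        stats::runif(1) < params$diagnostic_ion_fraction) {
      extra_mz <- diag_mz *
        (1 + (params$offset_ppm + stats::rnorm(1, 0, params$ppm_sigma)) * 1e-6)
      extra_int <- stats::rpois(1, 0.2 * params$mean_ions) + 1
    }
    nb <- params$n_backbone_peaks
    if (nb > 0) {
      extra_mz <- c(extra_mz, .rand_fragment_mz(nb))
      extra_int <- c(extra_int, stats::rlnorm(nb, log(params$mean_ions / 20),
                                              1))
    }
    nn <- params$n_noise_peaks
    if (nn > 0) {
      extra_mz <- c(extra_mz, .rand_fragment_mz(nn, lo = 140, hi = 1700))
      extra_int <- c(extra_int, stats::rexp(nn, 20 / params$mean_ions))
    }
    spectra[[i]] <- spectrum(
      spectrum_id = ids[i],
      precursor_mz = stats::runif(1, 400, 1200),
      mz = c(rep_mz, extra_mz),
      intensity = c(rep_int, pmax(extra_int, 1e-3)),
      charge = 2L,
      retention_time = stats::runif(1, 0, 1800),
      inv_k0 = stats::runif(1, 0.8, 1.3)
    )
  }
  list(
    spectra = spectra,
    truth = list(
      spectra = data.frame(spectrum_id = ids, feature_id = feature,
                           stringsAsFactors = FALSE),
      occupancy = occupancy,
      true_intensity = true_int,
      offset_ppm = params$offset_ppm
    )
  )
}

#' Simulate a single-cell quantification matrix with planted structure
#'
#' Log-normal baseline protein abundances; each cell gets a planted
#' cell-cycle stage whose panel markers are elevated `stage_effect`-fold;
#' a designated fraction of treated cells carries per-feature treatment
#' effects (uniform fold changes, or `exclusive` features expressed only in
#' the affected cells); detection is thinned by an abundance-dependent
#' logistic dropout so low-abundance signal goes missing first.
#' Deterministic given the seed.
#'
#' @param n_cells number of cells (split between conditions).
#' @param n_proteins total proteins (panel markers plus background).
#' @param panel a [marker_panel()] (default [synthetic_panel()]).
#' @param stage_effect fold elevation of a stage's markers in cells of that
#'   stage (default 4).
#' @param treatment_effects optional data.frame with columns `feature`
#'   (protein id, created if absent from the background set), `fold`
#'   (treated/control), `cell_fraction` (fraction of treated cells
#'   affected), `exclusive` (logical: feature absent everywhere else).
#' @param treated_fraction fraction of cells assigned to the treated
#'   condition (default 0.5).
#' @param dropout `NULL` for none, or `list(midpoint=, slope=)` of the
#'   logistic detection model `p = plogis(slope * log10(x / midpoint))`
#'   (default midpoint 20, slope 1.5).
#' @param base_meanlog,base_sdlog log-normal baseline across proteins
#'   (defaults `log(200)`, 1).
#' @param noise_sdlog per-measurement log-normal noise s.d. (default 0.35).
#' @param seed RNG seed.
#' @return list with `matrix` (a [quant_matrix()], all columns
#'   `single_cell`) and `truth` (data.frames `cells`: cell/condition/stage;
#'   `affected`: feature/cell for treatment plants).
#' @export
simulate_matrix <- function(n_cells = 100, n_proteins = 200,
                            panel = synthetic_panel(),
                            stage_effect = 4,
                            treatment_effects = NULL,
                            treated_fraction = 0.5,
                            dropout = list(midpoint = 20, slope = 1.5),
                            base_meanlog = log(200), base_sdlog = 1,
                            noise_sdlog = 0.35,
                            seed = 1L) {
  set.seed(seed)
  stages <- unique(panel$stage)
  n_bg <- max(0L, n_proteins - nrow(panel))
  proteins <- c(panel$protein, sprintf("P_%04d", seq_len(n_bg)))
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  n_treated <- round(treated_fraction * n_cells)
  condition <- rep(c("treated", "control"),
                   c(n_treated, n_cells - n_treated))
  stage <- sample(stages, n_cells, replace = TRUE)
  baseline <- stats::rlnorm(length(proteins), base_meanlog, base_sdlog)
  names(baseline) <- proteins
  vals <- baseline * matrix(stats::rlnorm(length(proteins) * n_cells,
                                          0, noise_sdlog),
                            length(proteins), n_cells)
  dimnames(vals) <- list(proteins, cells)
  for (st in stages) {
    markers <- panel$protein[panel$stage == st]
    in_stage <- stage == st
    vals[markers, in_stage] <- vals[markers, in_stage] * stage_effect
  }
  affected <- data.frame(feature = character(0), cell = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(treatment_effects)) {
    te <- treatment_effects
    if (is.null(te$exclusive)) te$exclusive <- FALSE
    treated_cells <- cells[condition == "treated"]
    for (r in seq_len(nrow(te))) {
      f <- te$feature[r]
      if (!f %in% proteins) {
        newrow <- stats::rlnorm(1, base_meanlog, base_sdlog) *
          stats::rlnorm(n_cells, 0, noise_sdlog)
        vals <- rbind(vals, matrix(newrow, 1, n_cells,
                                   dimnames = list(f, cells)))
        proteins <- c(proteins, f)
      }
      hit <- sample(treated_cells,
                    max(1L, round(te$cell_fraction[r] *
                                    length(treated_cells))))
      vals[f, hit] <- vals[f, hit] * te$fold[r]
      if (isTRUE(te$exclusive[r]))
        vals[f, setdiff(cells, hit)] <- NA_real_
      affected <- rbind(affected,
                        data.frame(feature = f, cell = hit,
                                   stringsAsFactors = FALSE))
    }
  }
  if (!is.null(dropout)) {
    p_det <- stats::plogis(dropout$slope *
                             log10(vals / dropout$midpoint))
    detected <- matrix(stats::runif(length(vals)) < p_det,
                       nrow(vals), ncol(vals))
    vals[!detected & !is.na(vals)] <- NA_real_
  }
  mat <- quant_matrix(
    vals,
    data.frame(run_id = "sim", label = cells, role = "single_cell",
               condition = condition, stringsAsFactors = FALSE)
  )
  list(
    matrix = mat,
    truth = list(
      cells = data.frame(cell = cells, condition = condition, stage = stage,
                         stringsAsFactors = FALSE),
      affected = affected
    )
  )
}
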