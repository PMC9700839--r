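design9 <- design_two_proteome()

mk_vec <- function(id, intensities) {
  x <- setNames(rep(NA_real_, nrow(design9)), design9$label)
  x[names(intensities)] <- intensities
  structure(list(spectrum_id = id, intensity = x,
                 matched_mz = ifelse(is.na(x), NA_real_, design9$mz)),
            class = "reporter_vector")
}

test_that("assembly sums PSM intensities per feature and channel", {
  vecs <- list(mk_vec("s1", c(`128N` = 100)), mk_vec("s2", c(`128N` = 50)),
               mk_vec("s3", c(`129N` = 7)))
  ids <- data.frame(spectrum_id = c("s1", "s2", "s3"),
                    feature_id = c("pepA", "pepA", "pepB"))
  m <- assemble(vecs, ids, design9, min_avg_intensity = 0)
  expect_equal(unname(m$values["pepA", grep("128N", colnames(m$values))]),
               150)
  expect_true(all(is.na(m$values["pepA", -grep("128N", colnames(m$values))])))
  expect_equal(unname(m$values["pepB", grep("129N", colnames(m$values))]), 7)
  expect_error(assemble(vecs, rbind(ids, ids[1, ]), design9),
               "duplicate")
})

test_that("low mean-intensity features are dropped at the threshold", {
  vecs <- list(mk_vec("s1", setNames(rep(9, 9), design9$label)),
               mk_vec("s2", setNames(rep(11, 9), design9$label)))
  ids <- data.frame(spectrum_id = c("s1", "s2"),
                    feature_id = c("low", "high"))
  m <- assemble(vecs, ids, design9, min_avg_intensity = 10)
  expect_setequal(rownames(m$values), "high")
})

test_that("random assembly equals the group-by-sum oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n <- 40
    vecs <- lapply(seq_len(n), function(i)
      random_reporter_vector(design9, id = paste0("s", i)))
    ids <- data.frame(
      spectrum_id = paste0("s", 1:n),
      feature_id = paste0("f", sample(8, n, replace = TRUE)))
    # a few unidentified spectra are ignored
    ids <- ids[-sample(n, 5), ]
    m <- assemble(vecs, ids, design9, min_avg_intensity = 0)
    truth <- oracle_assemble(vecs, ids, design9)
    expect_equal(unname(m$values), unname(truth[rownames(m$values), ]))
  }
})

test_that("channel exclusion removes columns and all-missing rows", {
  vals <- matrix(c(1, NA, 2, NA, NA, 3), 2, 3,
                 dimnames = list(c("a", "b"), NULL))
  m <- quant_matrix(vals, data.frame(run_id = "r",
                                     label = c("133N", "134N", "127N"),
                                     role = "standard"))
  out <- exclude_channels(m, c("133N", "134N"))
  expect_equal(ncol(out$values), 1)
  expect_equal(rownames(out$values), "b")  # 'a' is all-missing afterwards
  # row nonmissing only in an excluded channel is dropped
  vals2 <- matrix(c(5, 1, NA, 2), 2, 2,
                  dimnames = list(c("only133", "keep"), NULL))
  m2 <- quant_matrix(vals2, data.frame(run_id = "r",
                                       label = c("133N", "127N"),
                                       role = "standard"))
  out2 <- exclude_channels(m2, "133N")
  expect_equal(rownames(out2$values), "keep")
  expect_identical(exclude_channels(m, character(0)), m)
  expect_error(exclude_channels(m, "777X"), "unknown channels")
})

test_that("total-sum normalization equalizes selected column sums", {
  vals <- matrix(c(10, 90, 150, 150), 2, 2,
                 dimnames = list(c("a", "b"), NULL))
  m <- quant_matrix(vals, data.frame(run_id = "r", label = c("c1", "c2"),
                                     role = "single_cell"))
  out <- total_sum_normalize(m)
  expect_equal(colSums(out$values), c(r.c1 = 200, r.c2 = 200))
  # random matrices with missing values: all sums equal to 1e-9 relative
  set.seed(59)
  vals <- matrix(rexp(200), 20, 10)
  vals[sample(200, 30)] <- NA
  rownames(vals) <- paste0("f", 1:20)
  m2 <- quant_matrix(vals, data.frame(run_id = "r",
                                      label = paste0("c", 1:10),
                                      role = "single_cell"))
  out2 <- total_sum_normalize(m2)
  sums <- colSums(out2$values, na.rm = TRUE)
  expect_lt(diff(range(sums)) / mean(sums), 1e-9)
  # zero-sum column flagged, untouched
  vals3 <- matrix(c(1, 2, NA, NA), 2, 2,
                  dimnames = list(c("a", "b"), NULL))
  m3 <- quant_matrix(vals3, data.frame(run_id = "r", label = c("c1", "c2"),
                                       role = "single_cell"))
  out3 <- total_sum_normalize(m3)
  expect_equal(attr(out3, "unscaled"), "c2")
})

test_that("ratios: identity, capping, and one-group-only features", {
  vals <- matrix(c(10, 4, 10, 4, 10, NA, 10, NA), 2, 4,
                 dimnames = list(c("same", "only_a"), NULL))
  m <- quant_matrix(vals, data.frame(run_id = "r",
                                     label = c("a1", "a2", "b1", "b2"),
                                     role = "single_cell"))
  rt <- compute_ratios(m, c("r.a1", "r.a2"), c("r.b1", "r.b2"), cap = 100)
  expect_equal(rt$ratio[rt$feature_id == "same"], 1)
  # detected only in group a: reported at the cap (the 100-fold maximum)
  expect_equal(rt$ratio[rt$feature_id == "only_a"], 100)
  # antisymmetry up to capping
  rt_rev <- compute_ratios(m, c("r.b1", "r.b2"), c("r.a1", "r.a2"),
                           cap = 100)
  expect_equal(rt_rev$ratio[rt_rev$feature_id == "same"], 1)
  expect_equal(rt_rev$ratio[rt_rev$feature_id == "only_a"], 1 / 100)
})

test_that("pairwise-peptide rollup matches a hand-computed median", {
  # two peptides of one protein, 2 columns per group:
  # pep1: a=(4, 8), b=(2, 2) -> pairwise 2, 2, 4, 4
  # pep2: a=(9, NA), b=(3, 3) -> pairwise 3, 3
  # median of (2,2,4,4,3,3) = 3
  vals <- matrix(c(4, 9, 8, NA, 2, 3, 2, 3), 2, 4,
                 dimnames = list(c("pep1", "pep2"), NULL))
  m <- quant_matrix(vals, data.frame(run_id = "r",
                                     label = c("a1", "a2", "b1", "b2"),
                                     role = "single_cell"))
  fm <- data.frame(peptide_id = c("pep1", "pep2"),
                   feature_id = c("prot", "prot"))
  rt <- compute_ratios(m, c("r.a1", "r.a2"), c("r.b1", "r.b2"),
                       feature_map = fm)
  expect_equal(rt$ratio, 3)
  expect_equal(rt$n_obs, 6L)
  expect_lt(rt$p_value, 0.05)
  expect_error(compute_ratios(m, 1:2, 2:3), "disjoint")
})

test_that("PTM ratios are normalized by their parent protein ratio", {
  ptm <- data.frame(feature_id = c("siteA", "siteB", "orphan"),
                    ratio = c(4, 2, 5), p_value = NA_real_, n_obs = 1L)
  class(ptm) <- c("ratio_table", "data.frame"); attr(ptm, "cap") <- 100
  prot <- data.frame(feature_id = c("P1", "P2"), ratio = c(2, 2),
                     p_value = NA_real_, n_obs = 1L)
  map <- data.frame(ptm_id = c("siteA", "siteB"),
                    protein_id = c("P1", "P2"))
  expect_warning(out <- normalize_ptm_to_protein(ptm, prot, map),
                 "omitted")
  expect_equal(out$ratio[out$feature_id == "siteA"], 2)
  expect_equal(out$ratio[out$feature_id == "siteB"], 1)
  expect_false("orphan" %in% out$feature_id)
  # random tables equal elementwise division (within cap)
  set.seed(61)
  pr <- data.frame(feature_id = paste0("P", 1:20),
                   ratio = runif(20, 0.5, 2), p_value = NA, n_obs = 1L)
  pt <- data.frame(feature_id = paste0("s", 1:20),
                   ratio = runif(20, 0.5, 2), p_value = NA, n_obs = 1L)
  attr(pt, "cap") <- 100
  mp <- data.frame(ptm_id = paste0("s", 1:20),
                   protein_id = paste0("P", 1:20))
  out2 <- normalize_ptm_to_protein(pt, pr, mp)
  expect_equal(out2$ratio, pt$ratio / pr$ratio)
})

test_that("3-D export emits one row per feature-cell pair and pivots back", {
  vals <- matrix(c(1, 2, NA, 4, 5, 6), 2, 3,
                 dimnames = list(c("f1", "f2"), NULL))
  m <- quant_matrix(vals, data.frame(run_id = "r",
                                     label = c("c1", "c2", "c3"),
                                     role = "single_cell"))
  long <- export_3d(m, conditions = c("ctl", "ctl", "drug"))
  expect_equal(nrow(long), 6)
  expect_true(is.na(long$abundance[long$feature_id == "f1" &
                                     long$cell_index == 2]))
  expect_equal(long$log10_abundance, log10(long$abundance))
  back <- matrix(NA_real_, 2, 3, dimnames = list(c("f1", "f2"), NULL))
  for (i in seq_len(nrow(long)))
    back[long$feature_id[i], long$cell_index[i]] <- long$abundance[i]
  expect_equal(unname(back), unname(vals))
})
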