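design9 <- design_two_proteome()

test_that("extraction matches the 0.005 Da window contract", {
  # single peak near the 127N reporter (127.12476)
  s <- spectrum("s", 500, mz = 127.1248, intensity = 1000)
  v <- extract_reporters(s, design9, tol_value = 0.005, tol_unit = "Da")
  expect_equal(unname(v$intensity[["127N"]]), 1000)
  expect_true(all(is.na(v$intensity[setdiff(design9$label, "127N")])))
  # empty spectrum: everything missing
  v0 <- extract_reporters(spectrum("e", 500), design9)
  expect_true(all(is.na(v0$intensity)))
  # a peak just outside the window is not matched
  s2 <- spectrum("s2", 500, mz = 127.12476 + 0.0051, intensity = 10)
  v2 <- extract_reporters(s2, design9)
  expect_true(is.na(v2$intensity[["127N"]]))
})

test_that("extraction agrees with the exhaustive-scan oracle", {
  set.seed(31)
  for (rep in 1:200) {
    s <- random_spectrum(rpois(1, 30) + 1, mz_range = c(125, 137))
    tol <- sample(c(0.005, 0.003, 0.01), 1)
    v <- extract_reporters(s, design9, tol_value = tol, tol_unit = "Da")
    expect_equal(v$intensity, oracle_extract(s, design9, tol, "Da"))
  }
})

test_that("shrinking the tolerance never gains a match", {
  set.seed(37)
  for (rep in 1:50) {
    s <- random_spectrum(40, mz_range = c(125, 137))
    wide <- extract_reporters(s, design9, tol_value = 0.01)
    narrow <- extract_reporters(s, design9, tol_value = 0.002)
    gained <- !is.na(narrow$intensity) & is.na(wide$intensity)
    expect_false(any(gained))
  }
})

test_that("a peak between two channels goes to the nearer one only", {
  # TMT11 includes both 127N (127.12476) and 127C (127.13108), 0.0063 apart;
  # with a 0.005 Da window both windows cover a peak near the midpoint
  d <- plex_design(c("127N", "127C"), "standard", plex = "TMT11")
  peak <- mean(d$mz) + 0.0005  # slightly nearer 127C
  s <- spectrum("s", 500, mz = peak, intensity = 50)
  v <- extract_reporters(s, d, tol_value = 0.005)
  expect_true(is.na(v$intensity[["127N"]]))
  expect_equal(unname(v$intensity[["127C"]]), 50)
})

test_that("impurity correction inverts a known forward model", {
  set.seed(41)
  # hand-solved 2x2 with 10% leakage:
  # observed = [0.9 0.1; 0.1 0.9] %*% true, true = (100, 50)
  M2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  obs <- as.numeric(M2 %*% c(100, 50))
  v <- structure(list(spectrum_id = "s",
                      intensity = setNames(obs, c("A", "B")),
                      matched_mz = setNames(c(1, 2), c("A", "B"))),
                 class = "reporter_vector")
  out <- correct_impurities(v, M2)
  expect_equal(unname(out$intensity), c(100, 50), tolerance = 1e-8)
  # random diagonally dominant matrices: correct o apply = identity
  for (rep in 1:50) {
    M <- random_impurity_matrix(9)
    truth <- rexp(9, 1 / 300)
    vv <- structure(list(spectrum_id = "r",
                         intensity = setNames(apply_impurities(truth, M),
                                              design9$label),
                         matched_mz = setNames(design9$mz, design9$label)),
                    class = "reporter_vector")
    rec <- correct_impurities(vv, M)
    expect_equal(unname(rec$intensity), truth, tolerance = 1e-6)
  }
})

test_that("identity impurities return the input; missing stays missing", {
  v <- random_reporter_vector(design9, p_missing = 0.4)
  out <- correct_impurities(v, diag(9))
  expect_identical(out$intensity, v$intensity)
  M <- random_impurity_matrix(9)
  out2 <- correct_impurities(v, M)
  expect_identical(is.na(out2$intensity), is.na(v$intensity))
  expect_error(correct_impurities(v, matrix(0.5, 9, 9)), "singular")
})

test_that("impurity matrix validation enforces the documented invariants", {
  M <- random_impurity_matrix(4)
  expect_silent(validate_impurity_matrix(M))
  bad <- M; bad[1, 2] <- 1.2
  expect_error(validate_impurity_matrix(bad), "\\[0, 1\\]")
  bad2 <- M; bad2[, 1] <- c(0.2, 0.4, 0.2, 0.3)
  expect_error(validate_impurity_matrix(bad2), "dominant|sums")
})

test_that("interference-free index follows its defining formula", {
  m <- quant_matrix(
    matrix(c(0, 100, 50, 50, 100, 100), 1,
           dimnames = list("pep1", NULL)),
    data.frame(run_id = "r", label = c("ko1", "ko2", "p1", "p2", "p3", "p4"),
               role = "standard")
  )
  # ko mean 50, parent mean 75 -> IFI = 1/3
  expect_equal(
    interference_free_index(m, c("ko1", "ko2"), c("p1", "p2", "p3", "p4")),
    c(pep1 = 1 - 50 / 75))
  # zero ko -> 1; ko == parent -> 0; zero parent -> NA
  vals <- matrix(c(0, 10, 10, 10, 5, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  m2 <- quant_matrix(vals, data.frame(run_id = "r", label = c("ko", "p"),
                                      role = "standard"))
  ifi <- interference_free_index(m2, "ko", "p")
  expect_equal(unname(ifi), c(1, 0, NA_real_))
  expect_error(interference_free_index(m2, "ko", "ko"), "disjoint")
  # random matrices: equals direct formula evaluation, clamped
  set.seed(43)
  vals <- matrix(rexp(300), 50, 6)
  rownames(vals) <- paste0("f", 1:50)
  m3 <- quant_matrix(vals, data.frame(run_id = "r",
                                      label = c("k1", "k2", "p1", "p2",
                                                "p3", "p4"),
                                      role = "standard"))
  got <- interference_free_index(m3, c("k1", "k2"), c("p1", "p2", "p3", "p4"))
  manual <- pmin(pmax(1 - rowMeans(vals[, 1:2]) / rowMeans(vals[, 3:6]), 0), 1)
  expect_equal(got, manual)
})

test_that("diagnostic-ion detection separates 126.0913 from the reporter", {
  diag_mz <- diagnostic_ions()$mz[1]
  rep_mz <- reporter_channels()$mz[1]
  s <- spectrum("s", 500, mz = c(diag_mz, rep_mz), intensity = c(10, 1000))
  hit <- detect_diagnostic_ion(s, diag_mz, tol_ppm = 50,
                               exclusion_mz = rep_mz)
  expect_equal(hit$mz, diag_mz)
  expect_equal(hit$intensity, 10)
  # no peak near the diagnostic mass
  s2 <- spectrum("s2", 500, mz = rep_mz, intensity = 1000)
  expect_null(detect_diagnostic_ion(s2, diag_mz, 50, rep_mz))
  # a window reaching the exclusion mass is refused (gap is ~289 ppm)
  expect_error(detect_diagnostic_ion(s, diag_mz, tol_ppm = 400,
                                     exclusion_mz = rep_mz),
               "smaller tolerance")
})

test_that("diagnostic detection agrees with nearest-peak classification", {
  diag_mz <- diagnostic_ions()$mz[1]
  rep_mz <- reporter_channels()$mz[1]
  set.seed(47)
  for (rep in 1:200) {
    s <- random_spectrum(rpois(1, 10) + 1, mz_range = c(126.05, 126.17))
    hit <- detect_diagnostic_ion(s, diag_mz, tol_ppm = 100,
                                 exclusion_mz = rep_mz)
    w <- diag_mz * 100e-6
    cand <- which(abs(s$mz - diag_mz) <= w &
                    abs(s$mz - diag_mz) < abs(s$mz - rep_mz))
    if (!length(cand)) {
      expect_null(hit)
    } else {
      expect_equal(hit$intensity, max(s$intensity[cand]))
    }
  }
})
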