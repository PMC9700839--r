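# independent brute-force oracles and small random generators shared by the
# unit tests; each oracle is a direct restatement of the operation's
# definition, independent of the implementation path it checks

random_spectrum <- function(n_peaks, id = "s1", mz_range = c(100, 1700)) {
  spectrum(
    spectrum_id = id,
    precursor_mz = runif(1, 400, 1200),
    mz = runif(n_peaks, mz_range[1], mz_range[2]),
    intensity = rexp(n_peaks, 1 / 100),
    charge = 2L,
    retention_time = runif(1, 0, 1800),
    inv_k0 = runif(1, 0.8, 1.3)
  )
}

# sort-and-slice definition of the top-n filter
oracle_top_n <- function(spec, n) {
  if (length(spec$mz) <= n) return(cbind(spec$mz, spec$intensity))
  o <- order(-spec$intensity, spec$mz)[seq_len(n)]
  keep <- sort(o)
  cbind(spec$mz[keep], spec$intensity[keep])
}

# exhaustive scan over all (peak, channel) pairs
oracle_extract <- function(spec, design, tol_value, tol_unit = "Da") {
  theo <- design$mz
  width <- if (tol_unit == "ppm") theo * tol_value * 1e-6
           else rep(tol_value, length(theo))
  res <- setNames(rep(NA_real_, length(theo)), design$label)
  if (!length(spec$mz)) return(res)
  # peak -> owning channel (nearest among in-window channels)
  owner <- rep(NA_integer_, length(spec$mz))
  for (p in seq_along(spec$mz)) {
    d <- abs(spec$mz[p] - theo)
    ok <- which(d <= width)
    if (length(ok)) owner[p] <- ok[which.min(d[ok])]
  }
  for (k in seq_along(theo)) {
    mine <- which(owner == k & spec$intensity > 0)
    if (!length(mine)) next
    mine <- mine[order(-spec$intensity[mine],
                       abs(spec$mz[mine] - theo[k]))]
    res[k] <- spec$intensity[mine[1]]
  }
  res
}

# per-window sort definition of bin_top_k
oracle_bin_top_k <- function(spec, k, window) {
  keep <- integer(0)
  for (b in unique(floor(spec$mz / window))) {
    ix <- which(floor(spec$mz / window) == b)
    ix <- ix[order(-spec$intensity[ix], spec$mz[ix])]
    keep <- c(keep, ix[seq_len(min(k, length(ix)))])
  }
  sort(keep)
}

# transitive closure (BFS) over the pairwise merge predicate
oracle_merge_groups <- function(records, rt_tol, im_tol, prec_tol) {
  n <- length(records)
  compat <- function(a, b) {
    abs(a$precursor_mz - b$precursor_mz) <= prec_tol &&
      abs(a$retention_time - b$retention_time) <= rt_tol &&
      abs(a$inv_k0 - b$inv_k0) <= im_tol
  }
  group <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(group[i])) next
    g <- g + 1L
    queue <- i
    group[i] <- g
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (is.na(group[j]) && compat(records[[cur]], records[[j]])) {
          group[j] <- g
          queue <- c(queue, j)
        }
      }
    }
  }
  group
}

# group-by-sum definition of matrix assembly (no intensity filter)
oracle_assemble <- function(vectors, id_table, design) {
  feats <- sort(unique(id_table$feature_id))
  out <- matrix(NA_real_, length(feats), nrow(design),
                dimnames = list(feats, design$label))
  for (v in vectors) {
    f <- id_table$feature_id[id_table$spectrum_id == v$spectrum_id]
    if (!length(f)) next
    for (ch in design$label) {
      x <- v$intensity[[ch]]
      if (!is.na(x))
        out[f, ch] <- (if (is.na(out[f, ch])) 0 else out[f, ch]) + x
    }
  }
  out
}

random_reporter_vector <- function(design, id = "v1", p_missing = 0.3) {
  x <- ifelse(runif(nrow(design)) < p_missing, NA_real_,
              rexp(nrow(design), 1 / 500))
  structure(
    list(spectrum_id = id,
         intensity = setNames(x, design$label),
         matched_mz = setNames(ifelse(is.na(x), NA_real_, design$mz),
                               design$label)),
    class = "reporter_vector"
  )
}

random_impurity_matrix <- function(n, max_leak = 0.08) {
  M <- diag(n)
  for (j in seq_len(n)) {
    leak <- runif(n, 0, max_leak)
    leak[j] <- 0
    M[, j] <- leak
    M[j, j] <- 1 - sum(leak)
  }
  M
}
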