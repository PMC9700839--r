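#' Construct an MS2 spectrum record
#'
#' A centroided tandem spectrum: precursor metadata plus a peak list kept
#' sorted ascending by m/z. `inv_k0` carries the trapped-ion-mobility
#' coordinate (reduced inverse mobility, 1/k0) when the acquisition provides
#' one.
#'
#' @param spectrum_id scan title / identifier.
#' @param precursor_mz precursor m/z (Th).
#' @param mz,intensity numeric vectors of equal length; peaks are re-sorted
#'   by m/z.
#' @param charge integer precursor charge, `NA` if unknown.
#' @param retention_time seconds, `NA` if unknown.
#' @param inv_k0 reduced inverse ion mobility, `NA` if absent.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, mz = numeric(0),
                     intensity = numeric(0), charge = NA_integer_,
                     retention_time = NA_real_, inv_k0 = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    if (anyNA(mz) || anyNA(intensity)) stop("peaks must not contain NA")
    if (any(mz <= 0)) stop("peak m/z must be positive")
    if (any(intensity < 0)) stop("peak intensity must be non-negative")
    o <- order(mz)
    mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  }
  if (!is.na(retention_time) && retention_time < 0)
    stop("retention_time must be >= 0")
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      precursor_mz = as.numeric(precursor_mz),
      charge = as.integer(charge),
      retention_time = as.numeric(retention_time),
      inv_k0 = as.numeric(inv_k0),
      mz = as.numeric(mz),
      intensity = as.numeric(intensity)
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum '%s'> precursor %.4f (z=%s) rt=%ss 1/k0=%s, %d peaks\n",
    x$spectrum_id, x$precursor_mz,
    ifelse(is.na(x$charge), "?", x$charge),
    ifelse(is.na(x$retention_time), "?", format(x$retention_time)),
    ifelse(is.na(x$inv_k0), "?", format(x$inv_k0)),
    length(x$mz)))
  invisible(x)
}

.num <- function(x) sprintf("%.6f", x)

#' Write spectra to an MGF file
#'
#' Emits standard `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`,
#' `CHARGE` and `RTINSECONDS` headers; 1/k0, when present, goes to a single
#' auxiliary `ION_MOBILITY` line. All numbers are printed with six decimal
#' places so that write-read-write is byte-stable.
#'
#' @param records list of [spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in records) {
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$spectrum_id),
      paste0("PEPMASS=", .num(s$precursor_mz))
    )
    if (!is.na(s$charge))
      lines <- c(lines, paste0("CHARGE=", abs(s$charge),
                               if (s$charge < 0) "-" else "+"))
    if (!is.na(s$retention_time))
      lines <- c(lines, paste0("RTINSECONDS=", .num(s$retention_time)))
    if (!is.na(s$inv_k0))
      lines <- c(lines, paste0("ION_MOBILITY=", .num(s$inv_k0)))
    lines <- c(lines,
               if (length(s$mz)) paste(.num(s$mz), .num(s$intensity)),
               "END IONS")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks into [spectrum()] records. Peaks are
#' sorted ascending by m/z; optional headers missing from a block become
#' `NA`. An `ION_MOBILITY` (or `1/K0`) header populates `inv_k0`.
#'
#' @param path MGF file path.
#' @return list of `spectrum` objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pm <- getv("PEPMASS")
    if (is.na(pm))
      stop("malformed MGF block ", b, ": missing PEPMASS")
    pm <- suppressWarnings(as.numeric(strsplit(pm, "[ \t]+")[[1]][1]))
    if (is.na(pm)) stop("malformed MGF block ", b, ": unparseable PEPMASS")
    ch <- getv("CHARGE")
    charge <- if (is.na(ch)) NA_integer_ else {
      sign <- if (grepl("-", ch, fixed = TRUE)) -1L else 1L
      sign * as.integer(gsub("[^0-9]", "", ch))
    }
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    im <- getv("ION_MOBILITY")
    if (is.na(im)) im <- getv("1/K0")
    im <- suppressWarnings(as.numeric(im))
    peak_lines <- block[!is_hdr]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[ \t]+")
      if (any(lengths(fields) < 2L))
        stop("malformed MGF block ", b, ": unparseable peak line")
      mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
      it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
      if (anyNA(mz) || anyNA(it))
        stop("malformed MGF block ", b, ": unparseable peak line")
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    title <- getv("TITLE")
    out[[b]] <- spectrum(
      spectrum_id = if (is.na(title)) paste0("index=", b) else title,
      precursor_mz = pm, mz = mz, intensity = it, charge = charge,
      retention_time = rt, inv_k0 = im
    )
  }
  out
}

#' Keep only the n most intense peaks of a spectrum
#'
#' The MSConvert-style noise filter: retain the `n` most intense fragment
#' ions (all peaks when fewer are present). Intensity ties are broken toward
#' lower m/z for determinism. Output stays sorted by m/z.
#'
#' @param spec a [spectrum()].
#' @param n positive integer, e.g. 200 for the standard conversion filter.
#' @return filtered `spectrum`; the input is not modified.
#' @export
top_n_filter <- function(spec, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  if (length(spec$mz) <= n) return(spec)
  o <- order(-spec$intensity, spec$mz)[seq_len(n)]
  keep <- sort(o)
  spec$mz <- spec$mz[keep]
  spec$intensity <- spec$intensity[keep]
  spec
}

# predicate: may records i and j be merged?
.merge_compatible <- function(a, b, rt_tol, im_tol, prec_tol) {
  if (abs(a$precursor_mz - b$precursor_mz) > prec_tol) return(FALSE)
  rta <- a$retention_time; rtb <- b$retention_time
  if (is.na(rta) != is.na(rtb)) return(FALSE)
  if (!is.na(rta) && abs(rta - rtb) > rt_tol) return(FALSE)
  ima <- a$inv_k0; imb <- b$inv_k0
  if (is.na(ima) != is.na(imb)) return(FALSE)
  if (!is.na(ima) && abs(ima - imb) > im_tol) return(FALSE)
  TRUE
}

#' Merge redundant MS2 spectra
#'
#' Combines repeat fragmentations of the same precursor, as done at MGF
#' conversion time: spectra whose precursor m/z, retention time and 1/k0 all
#' lie within the tolerances are merged (transitively within a connected
#' group). Within a group, peaks falling within `frag_tol` of one another are
#' combined by summing intensities at the intensity-weighted mean m/z;
#' merged precursor fields are intensity-weighted means over the group.
#'
#' @param records list of [spectrum()] objects.
#' @param rt_tol retention-time tolerance in seconds (default 5).
#' @param im_tol 1/k0 tolerance (default 0.1).
#' @param prec_tol precursor m/z tolerance in Da (default 0.05).
#' @param frag_tol fragment m/z matching tolerance in Da (default 0.01).
#' @return list of `spectrum` objects, length <= input length; unmerged
#'   records pass through unchanged.
#' @export
merge_redundant_spectra <- function(records, rt_tol = 5, im_tol = 0.1,
                                    prec_tol = 0.05, frag_tol = 0.01) {
  if (rt_tol < 0 || im_tol < 0 || prec_tol < 0 || frag_tol < 0)
    stop("tolerances must be non-negative")
  n <- length(records)
  if (n <= 1L) return(records)
  # union-find over the pairwise predicate
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (.merge_compatible(records[[i]], records[[j]],
                          rt_tol, im_tol, prec_tol)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- records[roots == r]
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- members[[1]]
      next
    }
    w <- vapply(members, function(s) sum(s$intensity), numeric(1))
    if (all(w == 0)) w <- rep(1, length(members))
    wmean <- function(f) {
      v <- vapply(members, function(s) f(s), numeric(1))
      if (all(is.na(v))) NA_real_ else sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)])
    }
    mz <- unlist(lapply(members, `[[`, "mz"))
    it <- unlist(lapply(members, `[[`, "intensity"))
    o <- order(mz); mz <- mz[o]; it <- it[o]
    # greedy single-linkage clustering along the m/z axis
    grp <- cumsum(c(1, diff(mz) > frag_tol))
    mmz <- vapply(split(seq_along(mz), grp), function(ix) {
      wi <- it[ix]
      if (sum(wi) == 0) mean(mz[ix]) else sum(mz[ix] * wi) / sum(wi)
    }, numeric(1))
    mit <- vapply(split(it, grp), sum, numeric(1))
    ch <- members[[1]]$charge
    out[[length(out) + 1L]] <- spectrum(
      spectrum_id = paste0(members[[1]]$spectrum_id, ";merged=",
                           length(members)),
      precursor_mz = wmean(function(s) s$precursor_mz),
      mz = mmz, intensity = mit,
      charge = ch,
      retention_time = wmean(function(s) s$retention_time),
      inv_k0 = wmean(function(s) s$inv_k0)
    )
  }
  out
}
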