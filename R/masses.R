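# Monoisotopic atomic masses (u), CODATA/AME2020. Isotopes other than the
# principal one are keyed by mass number, e.g. "13C", "15N".
.ATOMIC_MASS <- c(
  H    = 1.00782503207,
  `2H` = 2.01410177785,
  C    = 12.0,
  `13C` = 13.00335483507,
  N    = 14.0030740048,
  `15N` = 15.0001088989,
  O    = 15.9949146196,
  `18O` = 17.9991610,
  S    = 31.97207100,
  P    = 30.97376163
)

.ELECTRON_MASS <- 0.000548579909

#' Parse an elemental composition string
#'
#' Compositions use Hill-like notation with bracketed isotopes:
#' `"C8H16N"` is the TMT 126 reporter cation, `"C2[13C]6H16[15N]"` the 133N
#' reporter. A missing count means 1.
#'
#' @param formula character scalar.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  x <- gsub("[[:space:]]", "", formula)
  counts <- integer(0)
  pat <- "^(?:\\[([0-9]+)([A-Z][a-z]?)\\]|([A-Z][a-z]?))([0-9]*)"
  while (nzchar(x)) {
    m <- regmatches(x, regexec(pat, x, perl = TRUE))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop("cannot parse composition near: '", x, "'")
    elem <- if (nzchar(m[2])) paste0(m[2], m[3]) else m[4]
    n <- if (nzchar(m[5])) as.integer(m[5]) else 1L
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
    x <- substr(x, nchar(m[1]) + 1L, nchar(x))
  }
  counts
}

#' Monoisotopic mass of a composition
#'
#' @param composition a formula string or a named count vector as returned by
#'   [parse_formula()].
#' @return mass in u.
#' @export
formula_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  unknown <- setdiff(names(composition), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.ATOMIC_MASS[names(composition)] * composition)
}

#' Theoretical m/z of a singly charged cation
#'
#' The m/z of a reporter or diagnostic cation equals the monoisotopic mass of
#' its composition minus one electron mass (charge +1).
#'
#' @inheritParams formula_mass
#' @return m/z in Th.
#' @examples
#' channel_mz("C8H16N")     # TMT/TMTPro 126 reporter, 126.12772
#' channel_mz("C7H12NO")    # acetyl-lysine diagnostic ion, 126.0913
#' @export
channel_mz <- function(composition) {
  m <- formula_mass(composition)
  if (m <= 0) stop("composition is empty")
  m - .ELECTRON_MASS
}

# Reporter cation composition for a channel label. The unsubstituted reporter
# is C8H16N+; channel 126+m "N" carries (m-1) 13C plus one 15N, channel 126+m
# "C" carries m 13C. TMT 11-plex spans 126..131C, TMTPro (16/18-plex)
# 126..135N.
.reporter_composition <- function(label) {
  m <- regmatches(label, regexec("^(12[6-9]|13[0-5])([NC]?)$", label))[[1]]
  if (length(m) == 0L) stop("unrecognized channel label: ", label)
  shift <- as.integer(m[2]) - 126L
  kind <- m[3]
  if (shift == 0L) {
    n13c <- 0L; n15n <- 0L
  } else if (kind == "N") {
    n13c <- shift - 1L; n15n <- 1L
  } else if (kind == "C") {
    n13c <- shift; n15n <- 0L
  } else stop("channel label needs N/C suffix: ", label)
  paste0(
    if (8L - n13c > 0L) paste0("C", 8L - n13c) else "",
    if (n13c > 0L) paste0("[13C]", n13c) else "",
    "H16",
    if (n15n > 0L) "[15N]" else "N"
  )
}

.PLEX_LABELS <- list(
  TMT11 = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
            "130N", "130C", "131N", "131C"),
  TMTPro = c("126", "127N", "127C", "128N", "128C", "129N", "129C",
             "130N", "130C", "131N", "131C", "132N", "132C", "133N",
             "133C", "134N", "134C", "135N")
)

#' Reporter channel table for a reagent family
#'
#' Returns the packaged channel table: label, reporter cation composition,
#' and theoretical m/z, for TMT 11-plex or TMTPro (18 reporter masses).
#'
#' @param plex `"TMTPro"` (default) or `"TMT11"`.
#' @return data.frame with columns `label`, `composition`, `mz`, `plex`.
#' @export
reporter_channels <- function(plex = c("TMTPro", "TMT11")) {
  plex <- match.arg(plex)
  labels <- .PLEX_LABELS[[plex]]
  comp <- vapply(labels, .reporter_composition, character(1))
  data.frame(
    label = labels,
    composition = unname(comp),
    mz = vapply(comp, channel_mz, numeric(1), USE.NAMES = FALSE),
    plex = plex,
    stringsAsFactors = FALSE
  )
}

#' Diagnostic PTM marker ions
#'
#' Low-mass fragment cations whose presence in an MS2 spectrum flags a
#' modification; the acetyl-lysine ion at 126.0913 sits 0.0364 Th below the
#' 126 reporter.
#'
#' @return data.frame with columns `name`, `composition`, `mz`.
#' @export
diagnostic_ions <- function() {
  comp <- c(acetyl_lysine = "C7H12NO")
  data.frame(
    name = names(comp),
    composition = unname(comp),
    mz = vapply(comp, channel_mz, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Define a plex design
#'
#' A plex design assigns a role and (optionally) an expected relative amount
#' to each reporter channel of a run: `blank` (method blank well),
#' `single_cell`, `carrier`, `standard` (dilution/spike standards) or
#' `excluded`.
#'
#' @param labels channel labels, a subset of the reagent family's channels.
#' @param roles character vector, recycled, one role per channel.
#' @param expected_amount optional numeric vector of relative concentrations.
#' @param plex reagent family, `"TMTPro"` or `"TMT11"`.
#' @return data.frame of class `plex_design` with columns `label`, `role`,
#'   `expected_amount`, `mz`.
#' @export
plex_design <- function(labels, roles,
                        expected_amount = NA_real_,
                        plex = c("TMTPro", "TMT11")) {
  plex <- match.arg(plex)
  channels <- reporter_channels(plex)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  bad <- setdiff(labels, channels$label)
  if (length(bad))
    stop("labels not in ", plex, " table: ", paste(bad, collapse = ", "))
  roles <- rep_len(roles, length(labels))
  ok_roles <- c("blank", "single_cell", "carrier", "standard", "excluded")
  if (!all(roles %in% ok_roles))
    stop("roles must be one of: ", paste(ok_roles, collapse = ", "))
  if (sum(roles == "carrier") > 1L) stop("at most one carrier channel")
  d <- data.frame(
    label = labels,
    role = roles,
    expected_amount = rep_len(as.numeric(expected_amount), length(labels)),
    mz = channels$mz[match(labels, channels$label)],
    stringsAsFactors = FALSE
  )
  attr(d, "plex") <- plex
  class(d) <- c("plex_design", "data.frame")
  d
}

#' Read a plex design from delimited text
#'
#' Expects columns `label` and `role`, optionally `expected_amount` and
#' `plex` (first value used).
#'
#' @param path file path to a TSV/CSV file.
#' @param sep field separator (default tab).
#' @return a [plex_design()].
#' @export
read_plex_design <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("label", "role") %in% names(d)))
    stop("design table needs 'label' and 'role' columns")
  plex_design(
    labels = as.character(d$label),
    roles = d$role,
    expected_amount = if ("expected_amount" %in% names(d))
      d$expected_amount else NA_real_,
    plex = if ("plex" %in% names(d)) d$plex[1] else "TMTPro"
  )
}
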