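# Monoisotopic atomic masses (Da) and M+1 isotopologue abundance ratios.
# M1 ratios are the per-atom abundance ratio of the +1 heavy isotope to the
# light one (13C/12C, 2H/1H, 15N/14N, 17O/16O, 33S/32S); P has no +1 isotope.

.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

.M1_RATIO <- c(
  C = 0.010816,
  H = 0.000115,
  N = 0.003653,
  O = 0.000380,
  P = 0.0,
  S = 0.007895
)

.PROTON_MASS <- .ATOMIC_MASS[["H"]] - 0.00054857990
.C13_SHIFT <- 1.0033548

.ELEMENTS <- names(.ATOMIC_MASS)

#' Parse a molecular formula string
#'
#' Parses a Hill-notation CHNOPS formula such as `"C5H9NO4"` into a named
#' integer vector of element counts.
#'
#' @param formula Character scalar, e.g. `"C12H22O11"`.
#' @return Named integer vector over C, H, N, O, P, S (zeros included).
#' @examples
#' parse_formula("C5H9NO4")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  rest <- formula
  pat <- "^([A-Z][a-z]?)([0-9]*)"
  while (nchar(rest) > 0L) {
    m <- regmatches(rest, regexec(pat, rest))[[1L]]
    if (length(m) == 0L || m[1L] == "") {
      stop("malformed formula: ", formula)
    }
    el <- m[2L]
    if (!el %in% .ELEMENTS) {
      stop("unsupported element '", el, "' in formula: ", formula)
    }
    n <- if (m[3L] == "") 1L else as.integer(m[3L])
    counts[el] <- counts[el] + n
    rest <- substring(rest, nchar(m[1L]) + 1L)
  }
  counts
}

#' Format element counts as a formula string
#'
#' @param counts Named numeric vector of element counts (subset of CHNOPS).
#' @return Character scalar in Hill order (C, H, then alphabetical).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  ord <- c("C", "H", setdiff(sort(names(counts)), c("C", "H")))
  ord <- ord[ord %in% names(counts)]
  paste0(vapply(ord, function(el) {
    if (counts[[el]] == 1) el else paste0(el, counts[[el]])
  }, character(1L)), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' @param formula Formula string or named count vector.
#' @return Monoisotopic (exact) mass in Da.
#' @examples
#' monoisotopic_mass("C5H9NO4") # glutamate, 147.0532
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

#' Predicted M+1/M isotopologue intensity ratio
#'
#' First-order prediction of the relative abundance of the +1 Da
#' isotopologue (dominated by 13C at ~1.07% per carbon, with smaller
#' 15N, 33S, 2H and 17O contributions).
#'
#' @inheritParams monoisotopic_mass
#' @return Expected M+1/M intensity ratio.
#' @export
predict_m1_ratio <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.M1_RATIO[names(counts)] * counts)
}

#' Default adduct rule table
#'
#' Ion-type rules used to explain co-eluting features as adducts, multimers
#' or (de)protonated molecules of a common neutral mass M. A rule maps M to
#' an observed m/z as `(multiplicity * M + mass_shift) / charge`. The
#' default set covers positive mode ([M+H]+, [M+NH4]+, [M+Na]+, [2M+H]+)
#' and negative mode ([M-H]-, [M+CH3COO]-, [2M-H]-); acetate is included
#' because HILIC mobile phases are typically ammonium acetate buffered.
#' Rules are in priority order; `primary` marks the ion species preferred
#' as a metabolite's characteristic (quantification) ion.
#'
#' @return data.frame with columns name, polarity, multiplicity,
#'   mass_shift, charge, primary.
#' @export
default_adduct_rules <- function() {
  data.frame(
    name = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[2M+H]+",
             "[M-H]-", "[M+CH3COO]-", "[2M-H]-"),
    polarity = c("positive", "positive", "positive", "positive",
                 "negative", "negative", "negative"),
    multiplicity = c(1L, 1L, 1L, 2L, 1L, 1L, 2L),
    mass_shift = c(.PROTON_MASS,
                   18.0338255,   # NH4+
                   22.9892213,   # Na+ (Na - e)
                   .PROTON_MASS,
                   -.PROTON_MASS,
                   59.0138536,   # CH3COO-
                   -.PROTON_MASS),
    charge = c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
    primary = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Read / write adduct rules
#'
#' Adduct rule tables are stored as CSV or YAML so users can edit the ion
#' chemistry without touching code.
#'
#' @param path File path; format chosen by extension (.csv/.tsv or
#'   .yml/.yaml).
#' @return `read_adduct_rules()` returns the rules data.frame.
#' @export
read_adduct_rules <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rules <- if (ext %in% c("yml", "yaml")) {
    lst <- yaml::read_yaml(path)
    do.call(rbind, lapply(lst, function(r) {
      data.frame(name = r$name, polarity = r$polarity,
                 multiplicity = as.integer(r$multiplicity),
                 mass_shift = as.numeric(r$mass_shift),
                 charge = as.integer(r$charge),
                 primary = isTRUE(r$primary),
                 stringsAsFactors = FALSE)
    }))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  }
  validate_adduct_rules(rules)
  rules
}

#' @rdname read_adduct_rules
#' @param rules Adduct rules data.frame.
#' @export
write_adduct_rules <- function(rules, path) {
  validate_adduct_rules(rules)
  ext <- tolower(tools::file_ext(path))
  # mass shifts written at fixed sub-nDa precision so rule tables
  # round-trip exactly enough for any m/z tolerance in use
  rules$mass_shift <- sprintf("%.9f", rules$mass_shift)
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(lapply(seq_len(nrow(rules)), function(i) {
      r <- as.list(rules[i, , drop = FALSE])
      r$mass_shift <- as.numeric(r$mass_shift)
      r
    }), path, precision = 12L)
  } else {
    sep <- if (ext == "csv") "," else "\t"
    utils::write.table(rules, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

validate_adduct_rules <- function(rules) {
  req <- c("name", "polarity", "multiplicity", "mass_shift", "charge",
           "primary")
  missing <- setdiff(req, names(rules))
  if (length(missing)) {
    stop("adduct rules lack columns: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(rules$polarity %in% c("positive", "negative")),
            all(rules$multiplicity >= 1L), all(rules$charge >= 1L))
  invisible(TRUE)
}
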