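# Elemental-composition arithmetic and the photoactivatable-ribonucleoside
# (PAR) adduct mass model.
#
# All masses are monoisotopic, in Da.  Compositions are named integer vectors
# (element symbol -> count); counts may be negative, which is how the
# Cys-adjusted adduct deltas are expressed (the crosslinked Cys is not
# carbamidomethylated, so the variable modification subtracts C2H3N1O1 from
# the generic delta).

# Standard monoisotopic atomic masses (CODATA/IUPAC), >= 6 decimals.
.ELEMENTS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

.PROTON <- 1.007276466812          # mass of H+ (not the hydrogen atom)
.WATER <- 2 * .ELEMENTS[["H"]] + .ELEMENTS[["O"]]

.CAM_FORMULA <- "C2H3N1O1"         # iodoacetamide carbamidomethylation
.RIBOSE_FORMULA <- "C5H8O4"        # neutral loss converting nucleoside -> base

# Residue (i.e. amino acid minus water) elemental compositions.
.RESIDUE_FORMULAS <- c(
  G = "C2H3N1O1",  A = "C3H5N1O1",  S = "C3H5N1O2",  P = "C5H7N1O1",
  V = "C5H9N1O1",  T = "C4H7N1O2",  C = "C3H5N1O1S1", L = "C6H11N1O1",
  I = "C6H11N1O1", N = "C4H6N2O2",  D = "C4H5N1O3",  Q = "C5H8N2O2",
  K = "C6H12N2O1", E = "C5H7N1O3",  M = "C5H9N1O1S1", H = "C6H7N3O1",
  F = "C9H9N1O1",  R = "C6H12N4O1", Y = "C9H9N1O2",  W = "C11H10N2O1"
)

#' Parse an elemental formula string into a composition vector
#'
#' Formulas are runs of an element symbol followed by an optional signed
#' integer count (default 1), e.g. \code{"C5H8O4"} or the Cys-adjusted adduct
#' \code{"C2H-1N1"}.  Whitespace is ignored.
#'
#' @param formula A single formula string.
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C2H-1N1")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  if (!nzchar(s)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?(-?[0-9]+)?", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse elemental formula: '", formula, "'")
  }
  elem <- sub("-?[0-9]+$", "", tokens)
  cnt_str <- substring(tokens, nchar(elem) + 1L)
  cnt <- ifelse(nzchar(cnt_str), suppressWarnings(as.numeric(cnt_str)), 1)
  unknown <- setdiff(unique(elem), names(.ELEMENTS))
  if (length(unknown)) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  out <- tapply(cnt, factor(elem, levels = unique(elem)), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Either a formula string (see [parse_formula()]) or a
#'   named numeric vector of element counts (may be negative).
#' @return Signed monoisotopic mass in Da.
#' @examples
#' mass_of("C5H8O4")   # ribose, ~132.0423
#' mass_of("C4H2N2O1") # 4SU-base adduct (minus H2S), rounds to 94
#' @export
mass_of <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0L) return(0)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of element counts")
  }
  unknown <- setdiff(names(composition), names(.ELEMENTS))
  if (length(unknown)) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  sum(composition * .ELEMENTS[names(composition)])
}

#' Combine two elemental compositions element-wise
#'
#' @param a,b Formula strings or named count vectors.
#' @param sign `+1` to add, `-1` to subtract `b`.
#' @return Named numeric composition vector (zero counts dropped).
#' @export
combine_compositions <- function(a, b, sign = 1) {
  if (is.character(a)) a <- parse_formula(a)
  if (is.character(b)) b <- parse_formula(b)
  elems <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(elems)), elems)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + sign * b
  out[out != 0]
}

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULAS, mass_of, numeric(1))
.CAM_MASS <- mass_of(.CAM_FORMULA)
.RIBOSE_MASS <- mass_of(.RIBOSE_FORMULA)

#' Mass of the ribose neutral loss (C5H8O4)
#' @return Monoisotopic mass in Da (~132.0423).
#' @export
ribose_mass <- function() .RIBOSE_MASS

#' Proton mass used for m/z conversions
#' @return Monoisotopic mass of H+ in Da.
#' @export
proton_mass <- function() .PROTON

#' Built-in PAR adduct definitions
#'
#' Elemental compositions of the crosslink adducts left on a peptide after
#' complete chemical (HF) digestion of the RNA, for 4-thiouridine (4SU) and
#' 6-thioguanosine (6SG).  Both forms have already lost H2S (the loss happens
#' during UVA crosslinking); the "base" form has additionally lost the ribose,
#' the "nucleoside" form retains it.  Compositions are for the 19 non-Cys
#' residues; the Cys delta is derived by subtracting the carbamidomethyl
#' composition (see [adduct_delta()]).
#'
#' @return data.frame with columns `par_type`, `form`, `formula`.
#' @export
default_adducts <- function() {
  data.frame(
    par_type = c("4SU", "4SU", "6SG", "6SG"),
    form = c("base", "nucleoside", "base", "nucleoside"),
    formula = c("C4H2N2O1", "C9H10N2O5", "C5H3N5", "C10H11N5O4"),
    stringsAsFactors = FALSE
  )
}

#' Read adduct definitions from a plain-text config
#'
#' A tab-separated file with header `par_type  form  formula` can override or
#' extend the built-in adduct table, so future photoactivatable analogs can be
#' added without a code change.
#'
#' @param path Path to the TSV file.
#' @return data.frame shaped like [default_adducts()].
#' @export
read_adduct_config <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("par_type", "form", "formula")
  if (!all(need %in% names(tab))) {
    stop("adduct config must have columns: ", paste(need, collapse = ", "))
  }
  for (f in tab$formula) parse_formula(f)  # validate early
  tab[, need]
}

.check_residue <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      !residue %in% names(.RESIDUE_FORMULAS)) {
    stop("not a standard amino-acid residue: '", residue, "'")
  }
  residue
}

#' Variable-modification mass delta of a PAR adduct on a given residue
#'
#' Returns the mass added to a peptide by a crosslinked PAR adduct (H2S loss
#' already included in the composition).  On Cys the delta is adjusted
#' downward by the carbamidomethyl mass because a crosslinked Cys is not
#' alkylated, while the fixed modification has been applied to every Cys:
#' `adduct_delta(p, f, "C") + mass_of("C2H3N1O1") == adduct_delta(p, f, "W")`.
#'
#' @param par_type `"4SU"` or `"6SG"` (or any `par_type` in `adducts`).
#' @param form `"base"` or `"nucleoside"`.
#' @param residue One-letter code of the crosslinked residue.
#' @param adducts Adduct definition table, see [default_adducts()].
#' @return Mass delta in Da.
#' @examples
#' round(adduct_delta("4SU", "base", "W"))        # 94
#' round(adduct_delta("6SG", "nucleoside", "Y"))  # 265
#' @export
adduct_delta <- function(par_type, form, residue, adducts = default_adducts()) {
  .check_residue(residue)
  row <- adducts$par_type == par_type & adducts$form == form
  if (sum(row) != 1L) {
    stop("no adduct definition for par_type='", par_type, "', form='", form, "'")
  }
  delta <- mass_of(adducts$formula[row])
  if (residue == "C") delta <- delta - .CAM_MASS
  delta
}

#' Neutral monoisotopic mass of a (possibly modified) peptide
#'
#' Sum of residue masses plus water, plus the fixed carbamidomethyl on every
#' Cys (if `carbamidomethyl = TRUE`), plus at most one variable PAR adduct.
#'
#' @param sequence Peptide sequence (standard one-letter codes).
#' @param mod_site Optional 1-based index of the crosslinked residue.
#' @param par_type,form Adduct identity when `mod_site` is given.
#' @param carbamidomethyl Apply the fixed Cys modification (default TRUE).
#' @param adducts Adduct definition table.
#' @return Neutral mass in Da.
#' @export
peptide_neutral_mass <- function(sequence, mod_site = NULL, par_type = NULL,
                                 form = NULL, carbamidomethyl = TRUE,
                                 adducts = default_adducts()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(res), names(.RESIDUE_FORMULAS))
  if (length(bad)) {
    stop("nonstandard residue in peptide: ", paste(bad, collapse = ", "))
  }
  mass <- sum(.RESIDUE_MASS[res]) + .WATER
  if (carbamidomethyl) mass <- mass + .CAM_MASS * sum(res == "C")
  if (!is.null(mod_site)) {
    if (length(mod_site) != 1L || is.na(mod_site) ||
        mod_site < 1L || mod_site > length(res)) {
      stop("modification site out of range for peptide '", sequence, "'")
    }
    mass <- mass + adduct_delta(par_type, form, res[mod_site], adducts)
  }
  mass
}

# Internal: per-residue mass vector with fixed carbamidomethyl applied to Cys.
.residue_mass_vector <- function(res, carbamidomethyl = TRUE) {
  m <- .RESIDUE_MASS[res]
  if (carbamidomethyl) m[res == "C"] <- m[res == "C"] + .CAM_MASS
  unname(m)
}
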