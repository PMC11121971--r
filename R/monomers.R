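#' Monomer registry
#'
#' Returns the registry of monomers available to the oligomer builder: three
#' diacids (adipic acid AA, 2,5-furandicarboxylic acid FDCA, terephthalic acid
#' TA), two diols/polyols used as chain extenders (1,4-butanediol BDO,
#' glycerol GLY), the polyol erythritol (ERY) and the diamine
#' 2,5-bis(aminomethyl)furan (DAF). The registry ships as a CSV asset under
#' `inst/extdata/monomers.csv`.
#'
#' Each row carries the monomer SMILES, a builder fragment (`frag`, the
#' left-to-right SMILES core whose terminal heteroatoms/carbonyls are the
#' condensation attachment points), the monomer class (`diacid`, `diol`,
#' `polyol`, `diamine`), the elemental formula and both mass conventions.
#'
#' @param ids optional character vector restricting the registry to these ids.
#' @return A data.frame, one row per monomer.
#' @export
#' @examples
#' monomer_registry(c("AA", "BDO"))
monomer_registry <- function(ids = NULL) {
  path <- system.file("extdata", "monomers.csv", package = "oligodeg")
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(ids)) {
    missing <- setdiff(ids, reg$id)
    if (length(missing)) {
      stop("unknown monomer id(s): ", paste(missing, collapse = ", "))
    }
    reg <- reg[match(ids, reg$id), , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' @rdname monomer_registry
#' @export
is_acyl_monomer <- function(ids) {
  monomer_registry(ids)$mclass == "diacid"
}

# masses used throughout: average atomic weights and monoisotopic masses
.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, F = 18.998, Cl = 35.45,
                     Br = 79.904, I = 126.904, Na = 22.990, K = 39.098)
.monoisotopic <- c(H = 1.007825, C = 12, N = 14.003074, O = 15.994915,
                   S = 31.972071, P = 30.973762, F = 18.998403,
                   Cl = 34.968853, Br = 78.918338, I = 126.904473,
                   Na = 22.989770, K = 38.963707)

#' Mass of the condensation water / end-group deltas
#'
#' Constants of the condensation arithmetic: one water is eliminated per
#' ester or amide bond; a methyl-ester end adds one CH2 relative to the free
#' acid.
#' @param convention `"average"` or `"monoisotopic"`.
#' @return Named numeric vector with elements `water`, `methyl`, `Na`, `H`, `K`.
#' @export
condensation_masses <- function(convention = c("average", "monoisotopic")) {
  convention <- match.arg(convention)
  w <- if (convention == "average") .atomic_weights else .monoisotopic
  c(water = unname(2 * w["H"] + w["O"]),
    methyl = unname(w["C"] + 2 * w["H"]),
    Na = unname(w["Na"]),
    H = unname(w["H"]),
    K = unname(w["K"]))
}

#' Parse an elemental formula into atom counts
#'
#' @param formula Hill-style formula string, e.g. `"C6H10O4"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts) || paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula)
  }
  els <- sub("[0-9]*$", "", parts)
  ns <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  counts <- vapply(split(ns, els), sum, numeric(1))
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts[order(names(counts))]
}

#' Molecular mass from an elemental formula
#'
#' @inheritParams parse_formula
#' @inheritParams condensation_masses
#' @return Mass in g/mol (average) or Da (monoisotopic).
#' @export
formula_mass <- function(formula, convention = c("average", "monoisotopic")) {
  convention <- match.arg(convention)
  w <- if (convention == "average") .atomic_weights else .monoisotopic
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown)) stop("no mass tabulated for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(w[names(counts)] * counts)
}
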