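#' Canonical SMILES
#'
#' Canonicalizes a SMILES string through OpenBabel (stereo-insensitive: any
#' stereo marks are stripped before canonicalization, since tetramer model
#' structures are built without assigned stereocenters).
#'
#' @param smiles character vector of SMILES strings.
#' @param strip_stereo drop stereochemistry before canonicalizing.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles, strip_stereo = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (strip_stereo) smiles <- gsub("[/\\\\]|@+", "", smiles)
  src <- paste0(paste(smiles, seq_along(smiles), sep = "\t"), "\n",
                collapse = "")
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles)) {
    stop("SMILES failed to parse: ",
         paste(utils::head(smiles, 3), collapse = ", "))
  }
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Structural identity of two SMILES
#'
#' Two line notations denote the same structure iff their canonical forms are
#' identical. Needed because printed SMILES are written in arbitrary atom
#' order and often read the chain in the opposite direction to its label.
#'
#' @param s1,s2 SMILES strings.
#' @inheritParams canonical_smiles
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' structures_equal("OCCO", "C(O)CO")
structures_equal <- function(s1, s2, strip_stereo = TRUE) {
  canonical_smiles(s1, strip_stereo) == canonical_smiles(s2, strip_stereo)
}

#' Formula and mass of a molecule given as SMILES
#'
#' Elemental formula via OpenBabel; average mass from the package atomic
#' weight table; monoisotopic mass via OpenBabel's exact-mass model.
#'
#' @param smiles a single SMILES string.
#' @return List with `formula`, `avg_mass` (g/mol), `mono_mass` (Da).
#' @export
#' @examples
#' molecular_formula_mass("OCC(O)CO")
molecular_formula_mass <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mols <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm\n"), identity)
  if (!length(mols)) stop("unparseable SMILES: ", smiles)
  props <- ChemmineOB::prop_OB(mols[[1]])
  if (!nzchar(props$formula)) stop("unparseable SMILES: ", smiles)
  list(formula = props$formula,
       avg_mass = formula_mass(props$formula, "average"),
       mono_mass = ChemmineOB::exactMass_OB(mols))
}

#' Oligomer sequence
#'
#' An ordered monomer sequence with linkage chemistry: the unit of structural
#' modelling. Units must strictly alternate between acyl (diacid) and
#' hydroxy/amino (diol, polyol, diamine) classes.
#'
#' @param units character vector of monomer ids, in chain order.
#' @param linkage `"ester"` or `"amide"`. Amide linkage requires every
#'   non-acyl slot to carry a diamine; ester mode refuses diamines.
#' @param end_policy terminal-group handling: `"free_acid_ol"` leaves free
#'   carboxylic acid / hydroxyl (or amine) ends, `"methyl_ester_end"`
#'   methylates one terminal acid, `"dimethyl_ester"` methylates every
#'   terminal acid.
#' @return An object of class `oligomer_sequence`.
#' @export
oligomer_sequence <- function(units,
                              linkage = c("ester", "amide"),
                              end_policy = c("free_acid_ol",
                                             "methyl_ester_end",
                                             "dimethyl_ester")) {
  linkage <- match.arg(linkage)
  end_policy <- match.arg(end_policy)
  if (length(units) < 2L) {
    stop("an oligomer sequence needs at least two units")
  }
  reg <- monomer_registry(units)
  acyl <- reg$mclass == "diacid"
  if (any(acyl[-1] == acyl[-length(acyl)])) {
    stop("units must strictly alternate acyl and hydroxy/amino monomers")
  }
  amine <- reg$mclass == "diamine"
  if (linkage == "ester" && any(amine)) {
    stop("diamine unit in ester mode; use linkage = \"amide\"")
  }
  if (linkage == "amide" && any(!acyl & !amine)) {
    stop("amide linkage requires diamines in every non-acyl slot")
  }
  structure(list(units = units, linkage = linkage, end_policy = end_policy),
            class = "oligomer_sequence")
}

#' @export
print.oligomer_sequence <- function(x, ...) {
  cat("<oligomer_sequence> ", paste(x$units, collapse = "-"),
      " [", x$linkage, ", ", x$end_policy, "]\n", sep = "")
  invisible(x)
}

#' Build a linear condensation oligomer
#'
#' Assembles the condensation product of an alternating acyl /
#' hydroxy(amino) monomer sequence, eliminating one water per bond. Glycerol
#' links through its two primary (1,3) hydroxyls and erythritol through its
#' two terminal primary hydroxyls, leaving the secondary hydroxyls free --
#' the regiochemistry of lipase-catalysed (CaLB) polycondensation. Terminal
#' acyl units keep a free carboxylic acid (or a methyl ester, per
#' `end_policy`); terminal diols keep a free primary hydroxyl.
#'
#' @param seq an [oligomer_sequence()], or a character vector of monomer ids
#'   (built with default linkage/end policy; linkage is inferred as amide
#'   when a diamine is present).
#' @return A `built_structure` list: canonical `smiles`, `formula`,
#'   `avg_mass`, `mono_mass`, `n_bonds` and the `source_sequence`.
#' @export
#' @examples
#' build_oligomer(c("AA", "BDO"))
build_oligomer <- function(seq) {
  if (is.character(seq)) {
    linkage <- if (any(monomer_registry(seq)$mclass == "diamine"))
      "amide" else "ester"
    seq <- oligomer_sequence(seq, linkage = linkage)
  }
  stopifnot(inherits(seq, "oligomer_sequence"))
  reg <- monomer_registry(seq$units)
  acyl <- reg$mclass == "diacid"
  n <- length(seq$units)

  left_cap <- right_cap <- ""
  methylate <- c(FALSE, FALSE) # left end, right end
  if (acyl[1]) left_cap <- "O"
  if (acyl[n]) right_cap <- "O"
  terminal_acids <- c(acyl[1], acyl[n])
  if (seq$end_policy == "dimethyl_ester") {
    if (!all(terminal_acids)) {
      stop("dimethyl_ester end policy needs acyl units at both ends")
    }
    methylate <- c(TRUE, TRUE)
  } else if (seq$end_policy == "methyl_ester_end") {
    if (!any(terminal_acids)) {
      stop("methyl_ester_end end policy needs a terminal acyl unit")
    }
    methylate <- if (terminal_acids[1]) c(TRUE, FALSE) else c(FALSE, TRUE)
  }
  if (methylate[1]) left_cap <- "CO"
  if (methylate[2]) right_cap <- "OC"

  smiles_raw <- paste0(left_cap, paste(reg$frag, collapse = ""), right_cap)
  smiles <- canonical_smiles(smiles_raw)

  masses <- condensation_masses("average")
  masses_m <- condensation_masses("monoisotopic")
  avg <- sum(reg$avg_mass) - (n - 1) * masses["water"] +
    sum(methylate) * masses["methyl"]
  mono <- sum(reg$mono_mass) - (n - 1) * masses_m["water"] +
    sum(methylate) * masses_m["methyl"]

  fm <- molecular_formula_mass(smiles)
  structure(list(smiles = smiles,
                 formula = fm$formula,
                 avg_mass = unname(avg),
                 mono_mass = unname(mono),
                 n_bonds = n - 1L,
                 source_sequence = seq),
            class = "built_structure")
}

#' @export
print.built_structure <- function(x, ...) {
  cat("<built_structure> ", paste(x$source_sequence$units, collapse = "-"),
      "\n  ", x$smiles, "\n  ", x$formula,
      sprintf("  avg %.2f g/mol, mono %.4f Da, %d bonds\n",
              x$avg_mass, x$mono_mass, x$n_bonds), sep = "")
  invisible(x)
}

#' Enumerate tetramer model sequences
#'
#' Generates all distinct four-unit alternating sequences over a monomer pool
#' under the composition patterns used for tetramer model structures:
#' `"ABAB"` (both monomers repeated twice), `"A1BA2B"` (two different acyl
#' units) and `"AB1AB2"` (two different hydroxy/amino units). Sequences are
#' deduplicated by canonical structure, so label reversals and pattern
#' overlaps collapse to one representative.
#'
#' @param pool character vector of monomer ids; must contain at least one
#'   acyl and one hydroxy/amino monomer.
#' @param patterns subset of `c("ABAB", "A1BA2B", "AB1AB2")`.
#' @return List of `oligomer_sequence` objects; each carries the canonical
#'   SMILES of its built structure as attribute `"smiles"`.
#' @export
enumerate_tetramers <- function(pool,
                                patterns = c("ABAB", "A1BA2B", "AB1AB2")) {
  patterns <- match.arg(patterns, several.ok = TRUE)
  reg <- monomer_registry(unique(pool))
  acids <- reg$id[reg$mclass == "diacid"]
  ols <- reg$id[reg$mclass != "diacid"]
  if (!length(acids) || !length(ols)) {
    stop("pool must contain at least one acyl and one hydroxy/amino monomer")
  }
  cand <- list()
  if ("ABAB" %in% patterns) {
    for (a in acids) for (b in ols) cand <- c(cand, list(c(a, b, a, b)))
  }
  if ("A1BA2B" %in% patterns) {
    for (a1 in acids) for (a2 in setdiff(acids, a1)) for (b in ols) {
      cand <- c(cand, list(c(a1, b, a2, b)))
    }
  }
  if ("AB1AB2" %in% patterns) {
    for (a in acids) for (b1 in ols) for (b2 in setdiff(ols, b1)) {
      cand <- c(cand, list(c(a, b1, a, b2)))
    }
  }
  seqs <- list()
  seen <- character(0)
  for (units in cand) {
    mixed <- any(monomer_registry(units)$mclass == "diamine") &&
      !all(monomer_registry(units)$mclass %in% c("diacid", "diamine"))
    if (mixed) next # ester/amide mixtures are out of scope
    linkage <- if (any(monomer_registry(units)$mclass == "diamine"))
      "amide" else "ester"
    sq <- oligomer_sequence(units, linkage = linkage)
    smi <- build_oligomer(sq)$smiles
    if (smi %in% seen) next
    seen <- c(seen, smi)
    attr(sq, "smiles") <- smi
    seqs <- c(seqs, list(sq))
  }
  seqs
}

#' Read and write one-record-per-line SMILES files
#'
#' The `.smi` dialect used here is `SMILES<TAB>id`, one record per line.
#'
#' @param path file path.
#' @return `read_smi`: data.frame with columns `smiles`, `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[[`, character(1), 1L),
             id = vapply(parts, function(p)
               if (length(p) > 1L) p[[2]] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param x data.frame with columns `smiles` and `id`.
#' @export
write_smi <- function(x, path) {
  writeLines(paste(x$smiles, x$id, sep = "\t"), path)
  invisible(path)
}
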