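#' Molecular surface descriptors
#'
#' Solvent-accessible surface areas by the numerical dot-density
#' (Shrake-Rupley) method with a 1.4 Angstrom water probe. The polar surface
#' area is the contribution of nitrogen, oxygen and their attached hydrogens;
#' the hydrophobic surface is the remainder, so `PSA + HSA = S` exactly by
#' construction.
#'
#' @param conf a `conformer3d`.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_dots test dots per atom sphere.
#' @return Named numeric vector `c(S=, PSA=, HSA=)` in Angstrom^2.
#' @export
surface_descriptors <- function(conf, probe_radius = 1.4, n_dots = 960) {
  stopifnot(inherits(conf, "conformer3d"))
  a <- conf$atoms
  r <- .atom_lj$radius[match(a$element, .atom_lj$element)]
  if (anyNA(r)) stop("no vdW radius for element(s): ",
                     paste(unique(a$element[is.na(r)]), collapse = ", "))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  per_atom <- sasa_dots(xyz, r + probe_radius, as.integer(n_dots))
  polar <- a$element %in% c("N", "O") | a$polar_h
  S <- sum(per_atom)
  PSA <- sum(per_atom[polar])
  c(S = S, PSA = PSA, HSA = S - PSA)
}

#' Topological polar surface area
#'
#' Alternative 2D (connectivity-based) polar surface area via OpenBabel's
#' TPSA contribution model, offered alongside the default 3D accessible-
#' surface PSA. Note the two conventions differ numerically; only the 3D
#' variant satisfies `PSA + HSA = S`.
#'
#' @param smiles a SMILES string.
#' @return TPSA in Angstrom^2.
#' @export
topological_psa <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm\n"), identity)
  if (!length(mols)) stop("unparseable SMILES: ", smiles)
  ChemmineOB::prop_OB(mols[[1]])$TPSA
}
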