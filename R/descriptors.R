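#' MIF engine configuration
#'
#' Tunable parameters of the descriptor engine: grid spacing and margin
#' (Angstrom), the upper energy clamp (kcal/mol), surface dot density, the
#' solvent probe radius and the probe parameter table.
#'
#' @param spacing grid node spacing, Angstrom.
#' @param margin grid margin beyond the molecular bounding box, Angstrom.
#' @param clamp upper field-energy clamp, kcal/mol.
#' @param n_dots surface test dots per atom.
#' @param probe_radius solvent probe radius for surfaces, Angstrom.
#' @param params probe parameter table ([probe_parameters()]).
#' @return A list of class `mif_config`.
#' @export
mif_config <- function(spacing = 0.5, margin = 6, clamp = 5,
                       n_dots = 960, probe_radius = 1.4,
                       params = probe_parameters()) {
  structure(list(spacing = spacing, margin = margin, clamp = clamp,
                 n_dots = n_dots, probe_radius = probe_radius,
                 params = params),
            class = "mif_config")
}

#' Names of the 18 selected descriptors, in canonical column order
#' @return Character vector of length 18.
#' @export
selected_descriptor_names <- function() {
  c(paste0("IW", 1:4), paste0("CW", 1:8),
    "logP", "PSA", "HSA", "MpKaA", "EMDIF", "EMDIS")
}

#' Most-acidic pKa estimate by functional-group rules
#'
#' Rule table: carboxylic acid 4.4, phenol 10.0, aliphatic alcohol 15.5,
#' amide N-H 16.5; molecules with none of these groups get the sentinel
#' 20.0. The most acidic (smallest) applicable value is returned.
#'
#' @param smiles a SMILES string.
#' @return pKa estimate (dimensionless).
#' @export
most_acidic_pka <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm\n"), identity)
  if (!length(mols)) stop("unparseable SMILES: ", smiles)
  rules <- list(c("[CX3](=O)[OX2H1]", 4.4),   # carboxylic acid
                c("c[OX2H1]", 10.0),          # phenol
                c("[CX4][OX2H1]", 15.5),      # aliphatic alcohol
                c("[CX3](=O)[NX3;H1,H2]", 16.5)) # amide N-H
  for (rule in rules) {
    hits <- ChemmineOB::smartsSearch_OB(mols, rule[[1]])
    if (hits > 0) return(as.numeric(rule[[2]]))
  }
  20.0
}

#' Octanol/water partition coefficient estimate
#'
#' Atomic-contribution (Crippen-type) logP via OpenBabel.
#'
#' @param smiles a SMILES string.
#' @return logP estimate.
#' @export
crippen_logp <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\tm\n"), identity)
  if (!length(mols)) stop("unparseable SMILES: ", smiles)
  ChemmineOB::prop_OB(mols[[1]])$logP
}

#' Compute the 18-descriptor vector for one molecule
#'
#' Embeds a seeded 3D conformer, computes the four probe fields (DRY, OH2,
#' O, N1) on one grid, and assembles the selected descriptors: integy
#' moments IW1-IW4 and capacity factors CW1-CW8 (hydrophilic volume per
#' total surface) from the water-probe field, logP, 3D polar and hydrophobic
#' surface areas, the most-acidic pKa rule value, and the polar/apolar
#' attraction-energy difference (EMDIF, polar minus apolar by convention)
#' and distance (EMDIS).
#'
#' @param smiles SMILES string, or a pre-embedded `conformer3d`.
#' @param config a [mif_config()].
#' @param seed embedding seed (ignored when a conformer is supplied).
#' @return Named numeric vector of length 18 in the order of
#'   [selected_descriptor_names()], with attributes `W` (hydrophilic
#'   volumes, Angstrom^3) and `S` (total surface, Angstrom^2).
#' @export
descriptor_vector <- function(smiles, config = mif_config(), seed = 1L) {
  if (inherits(smiles, "conformer3d")) {
    conf <- smiles
    smi <- conf$smiles
  } else {
    conf <- embed_3d(smiles, seed = seed)
    smi <- smiles
  }
  conf <- to_principal_frame(conf)
  grid <- grid_spec(conf, spacing = config$spacing, margin = config$margin)
  fields <- lapply(stats::setNames(nm = c("DRY", "OH2", "O", "N1")),
                   function(p) compute_field(conf, p, grid,
                                             params = config$params,
                                             clamp = config$clamp))
  vol <- grid_volume_descriptors(fields$OH2, conf)
  surf <- surface_descriptors(conf, probe_radius = config$probe_radius,
                              n_dots = config$n_dots)
  em <- em_descriptors(fields, conf)
  CW <- vol$W / surf[["S"]]
  names(CW) <- paste0("CW", 1:8)
  out <- c(vol$IW, CW,
           logP = crippen_logp(smi),
           PSA = unname(surf["PSA"]),
           HSA = unname(surf["HSA"]),
           MpKaA = most_acidic_pka(smi),
           EMDIF = unname(em["EMDIF"]),
           EMDIS = unname(em["EMDIS"]))
  out <- out[selected_descriptor_names()]
  attr(out, "W") <- vol$W
  attr(out, "S") <- unname(surf["S"])
  out
}

#' Compare two descriptor vectors for rigid-motion agreement
#'
#' Relative change per descriptor, with an absolute resolution floor below
#' which changes are not meaningful at the default grid: 0.1 Angstrom for
#' the length-type descriptors (IW, EMDIS; sub-voxel), 0.05 kcal/mol for
#' EMDIF, 0.005 for the dimensionless capacity factors, and none for the
#' large-magnitude descriptors (surfaces, logP, MpKaA). A descriptor
#' "agrees" when its change is at most `rel` of its magnitude or below the
#' floor.
#'
#' @param v1,v2 vectors from [descriptor_vector()].
#' @param rel relative-change threshold.
#' @return Named logical vector, `TRUE` where the pair agrees.
#' @export
descriptors_agree <- function(v1, v2, rel = 0.02) {
  nm <- selected_descriptor_names()
  floors <- c(rep(0.1, 4), rep(0.005, 8), 0, 0, 0, 0, 0.05, 0.1)
  names(floors) <- nm
  d <- abs(v1[nm] - v2[nm])
  ref <- pmax(abs(v1[nm]), abs(v2[nm]))
  d <= pmax(rel * ref, floors)
}

#' Descriptor matrix for a set of molecules
#'
#' Batch form of [descriptor_vector()]: embeds all molecules in one helper
#' call and returns a molecules-by-18 matrix.
#'
#' @param smiles character vector of SMILES.
#' @param ids row ids (defaults to the SMILES).
#' @param config a [mif_config()].
#' @param seed embedding seed shared by all molecules.
#' @return Numeric matrix with `ids` as rownames and the 18 selected
#'   descriptor columns.
#' @export
descriptor_matrix <- function(smiles, ids = smiles,
                              config = mif_config(), seed = 1L) {
  confs <- embed_3d_batch(smiles, seed = seed, ids = ids)
  rows <- lapply(seq_along(confs), function(i) {
    v <- descriptor_vector(confs[[i]], config = config)
    attributes(v)[c("W", "S")] <- NULL
    v
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  X
}

#' Write a descriptor matrix as CSV
#' @param X matrix from [descriptor_matrix()].
#' @param path output file.
#' @export
write_descriptor_csv <- function(X, path) {
  utils::write.csv(data.frame(id = rownames(X), X, check.names = FALSE,
                              row.names = NULL),
                   path, row.names = FALSE)
  invisible(path)
}
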