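#' Probe parameter table
#'
#' GRID-like parameters for the four interaction probes: DRY (hydrophobic),
#' OH2 (water), O (carbonyl oxygen, hydrogen-bond acceptor) and N1 (amide
#' nitrogen, hydrogen-bond donor). Columns: Lennard-Jones well depth `eps`
#' (kcal/mol) and radius `radius` (Angstrom), probe `charge` (e), hydrogen
#' bonding ability as donor/acceptor, and the H-bond well depth `hb_eps`
#' (kcal/mol). Values are literature-flavoured defaults, editable by passing
#' a modified copy to [compute_field()]; the DRY probe switches off
#' electrostatics and hydrogen bonding (pure dispersion/repulsion).
#'
#' @return data.frame keyed by probe name.
#' @export
probe_parameters <- function() {
  data.frame(
    probe = c("DRY", "OH2", "O", "N1"),
    eps = c(0.15, 0.15, 0.20, 0.16),
    radius = c(1.70, 1.55, 1.52, 1.55),
    charge = c(0, 0, -0.25, 0.25),
    donor = c(FALSE, TRUE, FALSE, TRUE),
    acceptor = c(FALSE, TRUE, TRUE, FALSE),
    hb_eps = c(0, 4.0, 4.0, 2.5),
    electrostatics = c(FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# per-element Lennard-Jones parameters (AMBER-flavoured)
.atom_lj <- data.frame(
  element = c("H", "C", "N", "O", "S", "F", "Cl", "Br", "P"),
  radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.47, 1.75, 1.85, 1.80),
  eps = c(0.0157, 0.086, 0.17, 0.21, 0.25, 0.061, 0.265, 0.32, 0.20),
  stringsAsFactors = FALSE
)

#' Grid specification for field sampling
#'
#' A regular Cartesian grid enclosing a conformer with a margin on every
#' side. The margin must cover the probe interaction range so fields decay
#' toward zero at the box boundary.
#'
#' @param conf a `conformer3d` (ignored if `origin` and `dims` are given).
#' @param spacing node spacing, Angstrom (must be positive and, for field
#'   computation, at most 1.0).
#' @param margin box margin beyond the atomic bounding box, Angstrom.
#' @param origin,dims explicit origin and node counts, overriding the
#'   conformer-derived box.
#' @return A `grid_spec` list: `origin`, `spacing`, `dims`, `margin`.
#' @export
grid_spec <- function(conf = NULL, spacing = 0.5, margin = 6,
                      origin = NULL, dims = NULL) {
  stopifnot(spacing > 0)
  if (is.null(origin) || is.null(dims)) {
    stopifnot(inherits(conf, "conformer3d"))
    xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
    lo <- apply(xyz, 2, min) - margin
    hi <- apply(xyz, 2, max) + margin
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  }
  structure(list(origin = unname(origin), spacing = spacing,
                 dims = as.integer(dims), margin = margin),
            class = "grid_spec")
}

#' Node coordinates of a grid (x varies fastest)
#' @param grid a `grid_spec`.
#' @return Matrix with one xyz row per node.
#' @export
grid_nodes <- function(grid) {
  g <- expand.grid(
    x = grid$origin[1] + (seq_len(grid$dims[1]) - 1L) * grid$spacing,
    y = grid$origin[2] + (seq_len(grid$dims[2]) - 1L) * grid$spacing,
    z = grid$origin[3] + (seq_len(grid$dims[3]) - 1L) * grid$spacing
  )
  as.matrix(g)
}

#' Compute a molecular interaction field
#'
#' Samples the probe-molecule interaction energy on a regular grid. For the
#' polar probes (OH2, O, N1) the energy at a node is the sum over atoms of a
#' Lennard-Jones 12-6 term, a Coulomb term with distance-dependent dielectric
#' (eps(r) = 4r), and a 12-10 hydrogen-bond enhancement for complementary
#' donor/acceptor pairs. The DRY probe uses the hydrophobic formulation:
#' dispersion attraction with the repulsive core, no electrostatics and no
#' hydrogen bonding. Energies are clamped from above at `clamp` kcal/mol.
#'
#' @param conf a `conformer3d`.
#' @param probe one of `"DRY"`, `"OH2"`, `"O"`, `"N1"`.
#' @param grid a [grid_spec()]; defaults to the conformer box at 0.5 Angstrom
#'   spacing with a 6 Angstrom margin.
#' @param params probe parameter table, see [probe_parameters()].
#' @param clamp upper energy clamp, kcal/mol.
#' @return A `probe_field` list: `probe`, `grid`, `energies` (kcal/mol, one
#'   value per node, x fastest).
#' @export
compute_field <- function(conf, probe, grid = NULL,
                          params = probe_parameters(), clamp = 5) {
  stopifnot(inherits(conf, "conformer3d"))
  probe <- match.arg(probe, params$probe)
  if (is.null(grid)) grid <- grid_spec(conf)
  if (grid$spacing > 1.0) {
    stop("grid spacing > 1.0 Angstrom is too coarse for volume descriptors")
  }
  p <- params[params$probe == probe, ]
  a <- conf$atoms
  lj <- .atom_lj[match(a$element, .atom_lj$element), ]
  if (anyNA(lj$radius)) {
    stop("no probe interaction parameters for element(s): ",
         paste(unique(a$element[is.na(lj$radius)]), collapse = ", "))
  }
  eps_pair <- sqrt(lj$eps * p$eps)
  rmin_pair <- lj$radius + p$radius
  qq <- if (p$electrostatics) 332.0636 * a$charge * p$charge else
    rep(0, nrow(a))
  # complementary hydrogen-bond pairing:
  #  - probe donor  ~ molecule acceptor heavy atoms (N, O), r0 = 2.9 A
  #  - probe acceptor ~ molecule polar hydrogens,            r0 = 1.9 A
  hb_eps <- rep(0, nrow(a))
  hb_r0 <- rep(2.9, nrow(a))
  if (p$hb_eps > 0) {
    if (p$donor) hb_eps[a$acceptor] <- p$hb_eps
    if (p$acceptor) {
      hb_eps[a$polar_h] <- p$hb_eps
      hb_r0[a$polar_h] <- 1.9
    }
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  energies <- field_energy_grid(xyz, eps_pair, rmin_pair, qq,
                                hb_eps, hb_r0,
                                grid$origin, grid$spacing, grid$dims,
                                diel_k = 4, clamp = clamp)
  structure(list(probe = probe, grid = grid, energies = energies),
            class = "probe_field")
}

#' @export
print.probe_field <- function(x, ...) {
  cat("<probe_field> ", x$probe, " probe, ",
      paste(x$grid$dims, collapse = "x"), " nodes @ ",
      x$grid$spacing, " A, E in [",
      sprintf("%.2f", min(x$energies)), ", ",
      sprintf("%.2f", max(x$energies)), "] kcal/mol\n", sep = "")
  invisible(x)
}

#' Energy cutoffs of the hydrophilic volume ladder
#'
#' The eight energy levels (kcal/mol) at which hydrophilic volumes W1..W8
#' are counted, following the published VolSurf convention; integy moments
#' use the first four.
#' @return Numeric vector of length 8.
#' @export
volume_cutoffs <- function() c(-0.2, -0.5, -1, -2, -3, -4, -5, -6)

#' Hydrophilic volumes and integy moments from a water-probe field
#'
#' `Wk` is the volume (node count times spacing cubed) of the region where
#' the water-probe energy is at or below cutoff `c_k`; `IWk` (k = 1..4) is
#' the distance from the molecular centre of mass to the energy-weighted
#' barycenter of that region (0 when the region is empty). The integy moment
#' measures the unbalance between the mass centre and the hydrophilic
#' regions.
#'
#' @param field an OH2 `probe_field`.
#' @param conf the `conformer3d` the field was computed from.
#' @return List with numeric vectors `W` (length 8, Angstrom^3) and `IW`
#'   (length 4, Angstrom).
#' @export
grid_volume_descriptors <- function(field, conf) {
  stopifnot(inherits(field, "probe_field"), inherits(conf, "conformer3d"))
  cuts <- volume_cutoffs()
  g <- field$grid
  summ <- level_set_summary(field$energies, g$origin, g$spacing, g$dims, cuts)
  W <- summ[, 1] * g$spacing^3
  com <- center_of_mass(conf)
  IW <- vapply(1:4, function(k) {
    if (summ[k, 1] == 0 || summ[k, 5] <= 0) return(0)
    bary <- summ[k, 2:4] / summ[k, 5]
    sqrt(sum((bary - com)^2))
  }, numeric(1))
  names(W) <- paste0("W", 1:8)
  names(IW) <- paste0("IW", 1:4)
  list(W = W, IW = IW)
}

#' Polar/apolar attraction-energy descriptors
#'
#' Each atom is scored by the lowest field energy within `atom_radius` of
#' its centre: its polar score is the minimum over the OH2, O and N1 fields,
#' its apolar score comes from the DRY field. EMDIF is the (signed, polar
#' minus apolar by convention) difference between the best polar and best
#' apolar atom scores -- i.e. between the strongest polar and apolar
#' interaction energies of the molecule. EMDIS is the distance between the
#' two atoms hosting those interactions. Both are 0 when either minimum is
#' above -0.2 kcal/mol. Scoring atoms by their local field minimum (rather
#' than mapping the single global minimum node back to an atom) keeps both
#' descriptors stable under rigid motion when several sites interact almost
#' equally well.
#'
#' @param fields named list of `probe_field`s for DRY, OH2, O, N1 on one grid.
#' @param conf the underlying `conformer3d`.
#' @param atom_radius radius (Angstrom) of the node neighbourhood scored to
#'   each atom; covers the hydrogen-bond and van der Waals contact shell.
#' @return Named numeric vector `c(EMDIF=, EMDIS=)`.
#' @export
em_descriptors <- function(fields, conf, atom_radius = 3.5) {
  need <- c("DRY", "OH2", "O", "N1")
  stopifnot(all(need %in% names(fields)))
  g <- fields$DRY$grid
  for (f in fields[need]) {
    if (!isTRUE(all.equal(f$grid$origin, g$origin)) ||
        !identical(f$grid$dims, g$dims)) {
      stop("probe fields must share one grid")
    }
  }
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  score <- function(field) {
    atom_region_min(field$energies, field$grid$origin, field$grid$spacing,
                    field$grid$dims, xyz, atom_radius)
  }
  pol_scores <- pmin(score(fields$OH2), score(fields$O), score(fields$N1))
  apol_scores <- score(fields$DRY)
  e_pol <- min(pol_scores)
  e_apol <- min(apol_scores)
  if (e_pol > -0.2 || e_apol > -0.2) {
    return(c(EMDIF = 0, EMDIS = 0))
  }
  # host atom = first atom scoring within a small margin of the best; the
  # margin absorbs grid noise between nearly tied sites and the atom-index
  # tie-break is frame-invariant, keeping EMDIS stable under rigid motion
  host <- function(scores, margin = 0.1) {
    which(scores <= min(scores) + margin)[1]
  }
  at_pol <- xyz[host(pol_scores), ]
  at_apol <- xyz[host(apol_scores), ]
  c(EMDIF = e_pol - e_apol,
    EMDIS = sqrt(sum((at_pol - at_apol)^2)))
}
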