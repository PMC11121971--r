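test_that("conformer embedding is deterministic per seed and well-formed", {
  c1 <- embed_3d("OCCO", seed = 7)
  c2 <- embed_3d("OCCO", seed = 7)
  expect_identical(c1$atoms, c2$atoms)
  c3 <- embed_3d("OCCO", seed = 8)
  expect_false(identical(c1$atoms, c3$atoms))
  expect_silent(validate_conformer(c1))

  # methane: carbon close to the centroid of all atoms
  m <- cached_confs()$methane
  expect_equal(nrow(m$atoms), 5L)
  centroid <- colMeans(as.matrix(m$atoms[, c("x", "y", "z")]))
  cpos <- unlist(m$atoms[m$atoms$element == "C", c("x", "y", "z")])
  expect_lt(sqrt(sum((cpos - centroid)^2)), 0.5)

  # O-C bond lengths in the standard range, brute force over close pairs
  g <- cached_confs()$glycol
  xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  for (i in which(g$atoms$element == "O")) {
    for (j in which(g$atoms$element == "C")) {
      if (d[i, j] < 1.6) expect_true(d[i, j] > 1.35 && d[i, j] < 1.50)
    }
  }
  expect_error(embed_3d("not_a_smiles"), "parse")
})

test_that("probe fields decay with distance and respect the clamp", {
  m <- cached_confs()$methane
  grid <- grid_spec(m, spacing = 0.9, margin = 16)
  f <- compute_field(m, "OH2", grid)
  nodes <- grid_nodes(grid)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  mind <- apply(nodes, 1, function(p) {
    min(sqrt(colSums((t(xyz) - p)^2)))
  })
  expect_lt(max(abs(f$energies[mind >= 15])), 0.01)
  expect_lte(max(f$energies), 5)

  # default margin: field near zero at the eight box corners
  for (cf in cached_confs()[c("glycerol", "hexane")]) {
    fd <- compute_field(cf, "OH2")
    d <- fd$grid$dims
    corner_idx <- c(1, d[1], (d[2] - 1) * d[1] + 1, d[1] * d[2])
    corner_idx <- c(corner_idx, prod(d) - corner_idx + 1)
    expect_lt(max(abs(fd$energies[corner_idx])), 0.05)
  }
  expect_error(compute_field(m, "OH2", grid_spec(m, spacing = 1.2)),
               "too coarse")
})

test_that("field minimum matches the Lennard-Jones closed form", {
  # single neutral carbon probed along a radial line, Coulomb off
  conf <- structure(list(atoms = data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 0,
    acceptor = FALSE, polar_h = FALSE), seed = 0, smiles = "C"),
    class = "conformer3d")
  params <- probe_parameters()
  p <- params[params$probe == "DRY", ]
  grid <- grid_spec(origin = c(2.0, 0, 0), dims = c(400L, 1L, 1L),
                    spacing = 0.005)
  f <- compute_field(conf, "DRY", grid, params = params)
  r <- 2.0 + (seq_len(400) - 1) * 0.005
  eps_pair <- sqrt(0.086 * p$eps)
  rmin_pair <- 1.70 + p$radius
  expect_equal(r[which.min(f$energies)], rmin_pair, tolerance = 0.01)
  expect_equal(min(f$energies), -eps_pair, tolerance = 1e-3)
})

test_that("benzene water field respects the ring symmetry", {
  bz <- cached_confs()$benzene
  v1 <- descriptor_vector(bz)
  # rotate by the C6 angle about the ring normal (third principal axis)
  ring <- as.matrix(bz$atoms[bz$atoms$element == "C", c("x", "y", "z")])
  eg <- eigen(stats::cov(ring), symmetric = TRUE)
  axis <- eg$vectors[, 3]
  th <- pi / 3
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R6 <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  v2 <- descriptor_vector(transform_conformer(bz, R6))
  expect_lt(max(abs(v2[c(paste0("CW", 1:8))] - v1[c(paste0("CW", 1:8))])),
            0.01)
  expect_lt(abs(v2["EMDIF"] - v1["EMDIF"]), 0.1)
})

test_that("hydrophilic volumes match a brute-force voxel count", {
  # hand-built 3x3x3 field with known node energies
  set.seed(5)
  energies <- round(stats::runif(27, -7, 1), 3)
  grid <- grid_spec(origin = c(0, 0, 0), dims = c(3L, 3L, 3L),
                    spacing = 0.5)
  field <- structure(list(probe = "OH2", grid = grid, energies = energies),
                     class = "probe_field")
  conf <- structure(list(atoms = data.frame(
    element = "C", x = 0.5, y = 0.5, z = 0.5, charge = 0,
    acceptor = FALSE, polar_h = FALSE), seed = 0, smiles = "C"),
    class = "conformer3d")
  out <- grid_volume_descriptors(field, conf)
  cuts <- volume_cutoffs()
  for (k in 1:8) {
    expect_equal(out$W[[k]], sum(energies <= cuts[k]) * 0.5^3)
  }
  # brute-force integy moment at level 1
  nodes <- grid_nodes(grid)
  sel <- energies <= cuts[1]
  w <- -energies[sel]
  bary <- colSums(nodes[sel, , drop = FALSE] * w) / sum(w)
  com <- center_of_mass(conf)
  expect_equal(unname(out$IW[[1]]), sqrt(sum((bary - com)^2)),
               tolerance = 1e-10)
  # nesting always holds
  expect_true(all(diff(out$W) <= 1e-12))

  # all-positive field: empty level sets are legal and give zeros
  field$energies <- abs(energies)
  out0 <- grid_volume_descriptors(field, conf)
  expect_true(all(out0$W == 0))
  expect_true(all(out0$IW == 0))
})

test_that("surface areas match the sphere closed form and split exactly", {
  lone <- structure(list(atoms = data.frame(
    element = "O", x = 1, y = -2, z = 0.3, charge = 0,
    acceptor = TRUE, polar_h = FALSE), seed = 0, smiles = "O"),
    class = "conformer3d")
  s <- surface_descriptors(lone)
  expect_equal(s[["S"]], 4 * pi * (1.52 + 1.4)^2,
               tolerance = 0.01)
  expect_equal(s[["PSA"]], s[["S"]])

  meth <- surface_descriptors(cached_confs()$methane)
  expect_equal(meth[["PSA"]], 0)
  expect_equal(meth[["HSA"]], meth[["S"]])
  gly <- surface_descriptors(cached_confs()$glycerol)
  expect_equal(gly[["PSA"]] + gly[["HSA"]], gly[["S"]])
})

test_that("attraction-energy descriptors follow their threshold rules", {
  # atoms separated beyond the per-atom scoring radius so each hosts only
  # the well built next to it
  grid <- grid_spec(origin = c(-1, -1, -1), dims = c(17L, 5L, 5L),
                    spacing = 0.5)
  conf <- structure(list(atoms = data.frame(
    element = c("O", "C"), x = c(0, 6), y = 0, z = 0,
    charge = 0, acceptor = c(TRUE, FALSE), polar_h = FALSE),
    seed = 0, smiles = "toy"), class = "conformer3d")
  mkfield <- function(probe, e) {
    structure(list(probe = probe, grid = grid, energies = e),
              class = "probe_field")
  }
  n <- prod(grid$dims)
  # polar wells beside the O atom, apolar well beside the C atom
  nodes <- grid_nodes(grid)
  pol <- rep(0, n); pol[which.min(rowSums(sweep(nodes, 2, c(0, 0, 0))^2))] <- -4
  apol <- rep(0, n); apol[which.min(rowSums(sweep(nodes, 2, c(6, 0, 0))^2))] <- -1
  fields <- list(DRY = mkfield("DRY", apol), OH2 = mkfield("OH2", pol),
                 O = mkfield("O", rep(0, n)), N1 = mkfield("N1", rep(0, n)))
  em <- em_descriptors(fields, conf)
  expect_equal(unname(em["EMDIF"]), -3)
  expect_equal(unname(em["EMDIS"]), 6) # the interatomic distance

  # no attractive apolar region -> both zero by the threshold rule
  fields$DRY <- mkfield("DRY", rep(0, n))
  expect_equal(unname(em_descriptors(fields, conf)), c(0, 0))

  # both minima hosted by the same atom -> zero distance
  fields$DRY <- mkfield("DRY", pol / 2)
  em2 <- em_descriptors(fields, conf)
  expect_equal(unname(em2["EMDIS"]), 0)

  # mismatched grids are refused
  g2 <- grid_spec(origin = c(0, 0, 0), dims = c(7L, 3L, 3L), spacing = 0.5)
  fields$DRY <- structure(list(probe = "DRY", grid = g2,
                               energies = rep(0, n)),
                          class = "probe_field")
  expect_error(em_descriptors(fields, conf), "share one grid")
})

test_that("descriptor vectors carry the 18 named values in fixed order", {
  v <- descriptor_vector(cached_confs()$glycerol)
  expect_identical(names(v), selected_descriptor_names())
  expect_false(any(is.na(v)))
  W <- attr(v, "W")
  expect_true(all(diff(W) <= 1e-9))
  expect_equal(unname(v[paste0("CW", 1:8)]), unname(W / attr(v, "S")))

  # acidity rules
  expect_equal(most_acidic_pka("OC(=O)c1ccc(o1)C(=O)O"), 4.4)
  expect_equal(most_acidic_pka("c1ccccc1O"), 10.0)
  expect_equal(most_acidic_pka("OCC(O)CO"), 15.5)
  expect_equal(most_acidic_pka("CC(=O)NC"), 16.5)
  expect_equal(most_acidic_pka("CCCC"), 20.0)

  # a polyol is more hydrophilic per surface than an alkane
  vg <- descriptor_vector(cached_confs()$glycerol)
  vh <- descriptor_vector(cached_confs()$hexane)
  expect_gt(vg["CW1"], vh["CW1"])
  expect_lt(vg["logP"], vh["logP"])
})

test_that("descriptors are invariant under rigid motion", {
  for (nm in c("glycerol", "ethanol", "hexane")) {
    cf <- cached_confs()[[nm]]
    v1 <- descriptor_vector(cf)
    cf2 <- transform_conformer(cf, random_rotation(match(nm, names(cached_confs()))),
                               c(3.2, -1.1, 0.7))
    v2 <- descriptor_vector(cf2)
    expect_true(all(descriptors_agree(v1, v2)),
                label = paste("rigid motion agreement for", nm))
  }
})

test_that("descriptor invariants hold across random small molecules", {
  smis <- unique(gen_random_smiles(40, seed = 19))
  confs <- embed_3d_batch(smis, seed = 3)
  for (cf in confs) {
    v <- descriptor_vector(cf)
    W <- attr(v, "W")
    expect_true(all(diff(W) <= 1e-9) && all(W >= 0))
    expect_equal(unname(v[paste0("CW", 1:8)]), unname(W / attr(v, "S")),
                 tolerance = 1e-12)
    s <- surface_descriptors(cf)
    expect_equal(s[["PSA"]] + s[["HSA"]], s[["S"]])
    expect_gte(v[["EMDIS"]], 0)
  }
})

test_that("halving the grid spacing changes volumes moderately", {
  fx <- load_fixtures()
  smi <- fx$table6$smiles[fx$table6$label == "BDO-FDCA-BDO-FDCA"]
  cf <- to_principal_frame(embed_3d(smi, seed = 4))
  w_of <- function(spacing) {
    f <- compute_field(cf, "OH2", grid_spec(cf, spacing = spacing))
    grid_volume_descriptors(f, cf)$W
  }
  w1 <- w_of(0.5)
  w2 <- w_of(0.25)
  rel <- abs(w2 - w1) / pmax(w1, 1)
  expect_lt(max(rel[1:6]), 0.10)
})
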