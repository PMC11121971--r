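#' Locate the Python interpreter used for conformer embedding
#'
#' The 3D embedding step runs RDKit's seeded distance-geometry algorithm
#' (ETKDGv3) through a bundled Python helper. Set the `OLIGODEG_PYTHON`
#' environment variable to override interpreter discovery.
#'
#' @return Path to a Python executable.
#' @export
oligodeg_python <- function() {
  env <- Sys.getenv("OLIGODEG_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no Python interpreter found; set OLIGODEG_PYTHON")
}

#' Embed seeded 3D conformers
#'
#' Generates one low-energy conformer per molecule by distance-geometry
#' embedding (RDKit ETKDGv3) followed by MMFF94 relaxation, with Gasteiger
#' partial charges (an iterative electronegativity-equalization scheme) and
#' hydrogen-bond role flags. Deterministic for a fixed seed; on embedding
#' failure the seed is incremented up to `max_retries` times and the seed
#' actually used is recorded.
#'
#' `embed_3d()` embeds a single molecule; `embed_3d_batch()` embeds many in
#' one interpreter call, which amortizes start-up cost.
#'
#' @param smiles SMILES string (or character vector for the batch form).
#' @param seed integer random seed for the distance-geometry embedding.
#' @param max_retries embedding retries (each bumps the seed by one).
#' @param ids optional molecule ids for the batch form.
#' @return A `conformer3d` object: data.frame `atoms` with columns `element`,
#'   `x`, `y`, `z` (Angstrom), `charge` (e), `acceptor`, `polar_h`, plus the
#'   `seed` used and the source `smiles`. The batch form returns a named list
#'   of `conformer3d` objects.
#' @export
embed_3d <- function(smiles, seed = 1L, max_retries = 5L) {
  embed_3d_batch(smiles, seed = seed, max_retries = max_retries)[[1]]
}

#' @rdname embed_3d
#' @export
embed_3d_batch <- function(smiles, seed = 1L, max_retries = 5L, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  tsv <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(tsv, out)), add = TRUE)
  writeLines(paste(ids, smiles, sep = "\t"), tsv)
  helper <- system.file("python", "embed_conformer.py", package = "oligodeg")
  status <- system2(oligodeg_python(),
                    c(shQuote(helper), shQuote(tsv), shQuote(out),
                      as.integer(seed), as.integer(max_retries)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out)) {
    stop("conformer embedding helper failed (exit status ", status, ")")
  }
  records <- jsonlite::fromJSON(readLines(out, warn = FALSE),
                                simplifyVector = FALSE)
  res <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    if (!identical(rec$status, "ok")) {
      stop("embedding failed for '", smiles[i], "': ", rec$status)
    }
    xyz <- do.call(rbind, lapply(rec$xyz, unlist))
    atoms <- data.frame(element = unlist(rec$element),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        charge = unlist(rec$charge),
                        acceptor = as.logical(unlist(rec$acceptor)),
                        polar_h = as.logical(unlist(rec$polar_h)),
                        stringsAsFactors = FALSE)
    structure(list(atoms = atoms, seed = rec$seed, smiles = smiles[i]),
              class = "conformer3d")
  })
  names(res) <- ids
  res
}

#' @export
print.conformer3d <- function(x, ...) {
  cat("<conformer3d> ", nrow(x$atoms), " atoms, seed ", x$seed, "\n",
      "  ", x$smiles, "\n", sep = "")
  invisible(x)
}

#' Validate a conformer
#'
#' Checks the structural invariants of a 3D conformer: finite coordinates,
#' near-zero (or integer) net charge, and no atom pair closer than 0.5
#' Angstrom.
#'
#' @param conf a `conformer3d`.
#' @param formal_charge expected net molecular charge.
#' @return `conf`, invisibly; errors on violation.
#' @export
validate_conformer <- function(conf, formal_charge = 0) {
  a <- conf$atoms
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  if (abs(sum(a$charge) - formal_charge) > 0.01) {
    stop("net partial charge deviates from formal charge")
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (nrow(xyz) > 1L) {
    d <- stats::dist(xyz)
    if (min(d) < 0.5) stop("atoms closer than 0.5 Angstrom")
  }
  invisible(conf)
}

# atomic masses for centre-of-mass computations
conformer_masses <- function(elements) {
  w <- .atomic_weights[elements]
  if (anyNA(w)) stop("no atomic weight for element(s): ",
                     paste(unique(elements[is.na(w)]), collapse = ", "))
  unname(w)
}

#' Centre of mass of a conformer
#' @param conf a `conformer3d`.
#' @return Numeric xyz vector (Angstrom).
#' @export
center_of_mass <- function(conf) {
  m <- conformer_masses(conf$atoms$element)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  colSums(xyz * m) / sum(m)
}

#' Rotate a conformer into its principal-axis body frame
#'
#' Centres the conformer at its centre of mass and aligns the mass-weighted
#' principal axes with the coordinate axes (largest spread first). Axis
#' ambiguities that rigid rotation cannot resolve -- the in-plane direction
#' of (near-)degenerate axis pairs in symmetric tops and the sign of each
#' axis -- are fixed from the atom list itself (lowest-index atom with a
#' clear projection), which depends only on atom order, never on the input
#' frame.
#' Grid-sampled descriptors computed in this body frame are invariant under
#' rigid motion of the input, because the sampling grid co-rotates with the
#' molecule.
#'
#' @param conf a `conformer3d`.
#' @return The conformer expressed in its body frame.
#' @export
to_principal_frame <- function(conf) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  m <- conformer_masses(conf$atoms$element)
  com <- colSums(xyz * m) / sum(m)
  X <- sweep(xyz, 2, com)
  C <- crossprod(X * sqrt(m / sum(m)))
  eig <- eigen(C, symmetric = TRUE)
  V <- eig$vectors # columns ordered by decreasing spread
  B <- X %*% V
  # symmetric tops have (near-)degenerate principal moments, leaving the
  # frame ambiguous within the degenerate plane; resolve it by pointing
  # the first ambiguous axis at the lowest-index atom with a significant
  # in-plane component (atom order does not depend on the input frame)
  lam <- eig$values
  for (d in 1:2) {
    if ((lam[d] - lam[d + 1]) / max(lam[1], 1e-8) < 0.05) {
      for (j in seq_len(nrow(B))) {
        u <- B[j, c(d, d + 1)]
        nu <- sqrt(sum(u^2))
        if (nu > 0.5) {
          u <- u / nu
          B[, c(d, d + 1)] <- B[, c(d, d + 1)] %*%
            cbind(c(u[1], u[2]), c(-u[2], u[1]))
          break
        }
      }
    }
  }
  # axis signs: orient each axis so the lowest-index atom with a clear
  # projection sits on the positive side (third coordinate moments vanish
  # for symmetric molecules, so they cannot fix the sign)
  for (d in 1:3) {
    j <- which(abs(B[, d]) > 0.1)[1]
    if (!is.na(j) && B[j, d] < 0) B[, d] <- -B[, d]
  }
  conf$atoms$x <- B[, 1]
  conf$atoms$y <- B[, 2]
  conf$atoms$z <- B[, 3]
  conf
}

#' Rigidly transform a conformer
#'
#' Applies a rotation (about the conformer centroid) and translation;
#' used to test rigid-motion invariance of the descriptors.
#'
#' @param conf a `conformer3d`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return The transformed `conformer3d`.
#' @export
transform_conformer <- function(conf, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  new <- sweep(sweep(xyz, 2, ctr) %*% t(rotation), 2, ctr + translation, "+")
  conf$atoms$x <- new[, 1]
  conf$atoms$y <- new[, 2]
  conf$atoms$z <- new[, 3]
  conf
}
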