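#' Peak list constructor
#'
#' An electrospray mass spectrum reduced to (m/z, abundance) pairs.
#'
#' @param mz m/z values, Th, all positive.
#' @param abundance abundances, arbitrary units, non-negative.
#' @return A `peak_list` data.frame.
#' @export
peak_list <- function(mz, abundance) {
  stopifnot(length(mz) == length(abundance))
  if (length(mz) && any(mz <= 0)) stop("m/z values must be positive")
  if (length(abundance) && any(abundance < 0)) {
    stop("abundances must be non-negative")
  }
  structure(data.frame(mz = as.numeric(mz),
                       abundance = as.numeric(abundance)),
            class = c("peak_list", "data.frame"))
}

#' Read/write two-column peak-list CSVs
#' @param path CSV with columns `mz`, `abundance`.
#' @return A `peak_list`.
#' @export
read_peaklist <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  peak_list(tab$mz, tab$abundance)
}

#' Number/weight-average molecular weights from an oligomer spectrum
#'
#' With `Ni` the abundance and `Mi = mz - adduct_mass` the neutral oligomer
#' mass of each peak: `Mn = sum(Ni Mi) / sum(Ni)`,
#' `Mw = sum(Ni Mi^2) / sum(Ni Mi)`, dispersity `D = Mw / Mn`.
#' Zero-abundance peaks are ignored.
#'
#' @param peaks a [peak_list()].
#' @param adduct_mass mass of the charge-carrying adduct subtracted from
#'   each m/z (default: sodium).
#' @return A `mass_summary` list: `Mn`, `Mw`, `dispersity` (all >= 1
#'   dispersity; Mw >= Mn by the Cauchy-Schwarz inequality).
#' @export
#' @examples
#' mass_summary(peak_list(c(400, 600), c(1, 1)), adduct_mass = 0)
mass_summary <- function(peaks, adduct_mass = condensation_masses()["Na"]) {
  stopifnot(inherits(peaks, "peak_list"))
  peaks <- peaks[peaks$abundance > 0, , drop = FALSE]
  if (!nrow(peaks)) stop("no peaks with positive abundance")
  mi <- peaks$mz - adduct_mass
  if (any(mi <= 0)) stop("negative neutral mass after adduct subtraction")
  ni <- peaks$abundance
  mn <- sum(ni * mi) / sum(ni)
  mw <- sum(ni * mi^2) / sum(ni * mi)
  structure(list(Mn = mn, Mw = mw, dispersity = mw / mn),
            class = "mass_summary")
}

#' @export
print.mass_summary <- function(x, ...) {
  cat(sprintf("<mass_summary> Mn %.2f, Mw %.2f, D %.4f\n",
              x$Mn, x$Mw, x$dispersity))
  invisible(x)
}

#' Truncate a dispersity the way printed tables do
#'
#' Published dispersity tables truncate (floor) `Mw/Mn` at two decimals
#' rather than rounding; this helper makes that convention explicit.
#' @param d dispersity value(s).
#' @param digits decimals kept.
#' @return Floored value(s).
#' @export
floor_dispersity <- function(d, digits = 2) floor(d * 10^digits) / 10^digits

#' Predict an adduct m/z series for alternating condensation oligomers
#'
#' For a chain of `n` alternating monomers drawn from an (acyl, hydroxy)
#' pair, the neutral mass is the monomer mass sum minus `(n-1)` waters, plus
#' one CH2 per methyl-ester end; the observed m/z adds the adduct mass.
#' Chains of every length `2..n_max` are enumerated with the acyl/hydroxy
#' counts differing by at most one (ceiling split to the first monomer).
#'
#' @param monomers character vector of two monomer ids (the alternating
#'   pair), or a named integer vector of monomer counts for a single
#'   composition.
#' @param end_group `"acid_ol"` (free ends), `"methyl_ester"` (one methyl
#'   ester end) or `"dimethyl_ester"`.
#' @param adduct `"Na"`, `"H"` or `"K"`.
#' @param n_max largest chain length (total monomer count), at least 2.
#' @param mass_convention `"average"` (unit-resolution ion trap default) or
#'   `"monoisotopic"`.
#' @return An `adduct_series` list with a `members` data.frame
#'   (`n_monomers`, `mz`) and the series metadata.
#' @export
#' @examples
#' predict_adduct_series(c("BDO", "FDCA"), end_group = "methyl_ester",
#'                       n_max = 8)
predict_adduct_series <- function(monomers,
                                  end_group = c("acid_ol", "methyl_ester",
                                                "dimethyl_ester"),
                                  adduct = c("Na", "H", "K"),
                                  n_max = 10L,
                                  mass_convention = c("average",
                                                      "monoisotopic")) {
  end_group <- match.arg(end_group)
  adduct <- match.arg(adduct)
  mass_convention <- match.arg(mass_convention)
  if (n_max < 2L) stop("n_max must be at least 2")
  cm <- condensation_masses(mass_convention)
  end_delta <- switch(end_group, acid_ol = 0, methyl_ester = cm[["methyl"]],
                      dimethyl_ester = 2 * cm[["methyl"]])
  mass_col <- if (mass_convention == "average") "avg_mass" else "mono_mass"

  if (!is.null(names(monomers)) && is.numeric(monomers)) {
    counts <- monomers
    if (!length(counts)) stop("empty composition")
    reg <- monomer_registry(names(counts))
    if (abs(sum(counts[reg$mclass == "diacid"]) -
            sum(counts[reg$mclass != "diacid"])) > 1) {
      stop("acyl and hydroxy/amino counts must differ by at most one")
    }
    n <- sum(counts)
    mz <- sum(reg[[mass_col]] * counts) - (n - 1) * cm[["water"]] +
      end_delta + cm[[adduct]]
    members <- data.frame(n_monomers = n, mz = mz)
  } else {
    if (length(monomers) != 2L) {
      stop("give two alternating monomer ids or a named count vector")
    }
    reg <- monomer_registry(monomers)
    if (sum(reg$mclass == "diacid") != 1L) {
      stop("the alternating pair needs exactly one acyl monomer")
    }
    n <- 2:n_max
    m1 <- ceiling(n / 2) * reg[[mass_col]][1]
    m2 <- floor(n / 2) * reg[[mass_col]][2]
    mz <- m1 + m2 - (n - 1) * cm[["water"]] + end_delta + cm[[adduct]]
    members <- data.frame(n_monomers = n, mz = mz)
  }
  structure(list(monomers = monomers, end_group = end_group,
                 adduct = adduct, mass_convention = mass_convention,
                 members = members),
            class = "adduct_series")
}

#' @export
print.adduct_series <- function(x, ...) {
  cat("<adduct_series> ", paste(x$monomers, collapse = "/"),
      " [", x$end_group, ", +", x$adduct, ", ", x$mass_convention, "]\n",
      sep = "")
  print(utils::head(x$members, 8))
  invisible(x)
}

#' Assign observed peaks to predicted adduct series
#'
#' Each peak is matched to the nearest predicted member across all candidate
#' series; matches farther than `tol_mz` are reported `unassigned`, and
#' peaks with members of two or more distinct series within `tol_mz` are
#' flagged `ambiguous`.
#'
#' @param peaks a [peak_list()].
#' @param candidates list of [predict_adduct_series()] results, optionally
#'   named.
#' @param tol_mz match tolerance, Th (1.0 suits unit-resolution spectra).
#' @return data.frame: `mz`, `abundance`, `series`, `n_monomers`,
#'   `predicted_mz`, `delta_mz`, `status`.
#' @export
assign_peaks <- function(peaks, candidates, tol_mz = 1.0) {
  stopifnot(inherits(peaks, "peak_list"), tol_mz > 0)
  if (inherits(candidates, "adduct_series")) candidates <- list(candidates)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    names(candidates) <- vapply(candidates, function(s)
      paste(s$monomers, collapse = "/"), character(1))
  }
  pred <- do.call(rbind, lapply(names(candidates), function(nm) {
    m <- candidates[[nm]]$members
    data.frame(series = nm, n_monomers = m$n_monomers, mz = m$mz,
               stringsAsFactors = FALSE)
  }))
  if (!nrow(peaks)) {
    return(data.frame(mz = numeric(0), abundance = numeric(0),
                      series = character(0), n_monomers = integer(0),
                      predicted_mz = numeric(0), delta_mz = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    d <- abs(pred$mz - peaks$mz[i])
    j <- which.min(d)
    within <- unique(pred$series[d <= tol_mz])
    status <- if (d[j] > tol_mz) "unassigned" else
      if (length(within) > 1L) "ambiguous" else "assigned"
    data.frame(mz = peaks$mz[i], abundance = peaks$abundance[i],
               series = if (status == "unassigned") NA_character_ else
                 pred$series[j],
               n_monomers = if (status == "unassigned") NA_integer_ else
                 pred$n_monomers[j],
               predicted_mz = if (status == "unassigned") NA_real_ else
                 pred$mz[j],
               delta_mz = if (status == "unassigned") NA_real_ else
                 peaks$mz[i] - pred$mz[j],
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
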