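#' Synthetic descriptor/response dataset with planted coefficients
#'
#' Generates a descriptor-like matrix from a correlated latent-factor model
#' (columns get heterogeneous scales, as mixed-unit descriptor blocks do)
#' and a linear response `y = X beta + N(0, noise_sd)` with a known sparse
#' coefficient vector. The planted truth is returned alongside so estimator
#' recovery can be scored against it. Pure given (config, seed): repeated
#' calls are identical.
#'
#' @param n_samples,n_descriptors matrix dimensions.
#' @param n_informative number of non-zero planted coefficients.
#' @param beta optional explicit planted coefficients (length
#'   `n_descriptors`); overrides `n_informative`.
#' @param noise_sd response noise standard deviation. When
#'   `noise_relative = TRUE` it is interpreted as a fraction of the noise-free
#'   signal standard deviation.
#' @param noise_relative see `noise_sd`.
#' @param n_factors latent factors driving descriptor correlation.
#' @param seed RNG seed.
#' @return List: `X` (named columns `V1..Vp`), `y`, `beta_true`, `config`.
#' @export
gen_pls_dataset <- function(n_samples = 100L, n_descriptors = 18L,
                            n_informative = 5L, beta = NULL,
                            noise_sd = 0.05, noise_relative = TRUE,
                            n_factors = 4L, seed = 1L) {
  stopifnot(n_informative <= n_descriptors, noise_sd >= 0)
  set.seed(seed)
  L <- matrix(stats::rnorm(n_samples * n_factors), n_samples)
  A <- matrix(stats::rnorm(n_factors * n_descriptors), n_factors)
  X <- L %*% A + 0.5 * matrix(stats::rnorm(n_samples * n_descriptors),
                              n_samples)
  col_scale <- 10^stats::runif(n_descriptors, -1, 2)
  X <- sweep(X, 2, col_scale, "*")
  colnames(X) <- paste0("V", seq_len(n_descriptors))
  if (is.null(beta)) {
    beta <- numeric(n_descriptors)
    idx <- sample.int(n_descriptors, n_informative)
    beta[idx] <- stats::rnorm(n_informative) / col_scale[idx]
  }
  signal <- drop(X %*% beta)
  sd_noise <- if (noise_relative) noise_sd * stats::sd(signal) else noise_sd
  y <- signal + stats::rnorm(n_samples, sd = sd_noise)
  list(X = X, y = y, beta_true = beta,
       config = list(n_samples = n_samples, n_descriptors = n_descriptors,
                     n_informative = n_informative, noise_sd = noise_sd,
                     noise_relative = noise_relative, n_factors = n_factors,
                     seed = seed))
}

#' Synthetic first-order BOD uptake curve
#'
#' Emulates closed-bottle respirometry output: a first-order oxygen uptake
#' with lag, `BOD(t) = (dt_inf/100) * thod * conc * (1 - exp(-k * max(t -
#' lag, 0)))`, plus a constant blank level and Gaussian noise. The noise-free
#' degradation-degree truth is returned alongside.
#'
#' @param times sampling days, strictly increasing.
#' @param dt_inf plateau degradation degree, percent (0..100).
#' @param k first-order rate, 1/day.
#' @param lag lag phase, days.
#' @param blank_level constant blank BOD, mg/L.
#' @param noise_sd measurement noise, mg/L.
#' @param thod theoretical oxygen demand, mg/mg.
#' @param conc substance concentration, mg/L.
#' @param seed RNG seed.
#' @param sample_id label for the series.
#' @return List: `series` (a [bod_series()] with the blank attached),
#'   `truth` (data.frame `times`, `dt`), `config`.
#' @export
gen_bod_series <- function(times = c(0, 2, 5, 7, 10, 14, 18, 21),
                           dt_inf = 50, k = 0.15, lag = 1,
                           blank_level = 2, noise_sd = 0,
                           thod = 1.5, conc = 100, seed = 1L,
                           sample_id = "synthetic") {
  stopifnot(dt_inf >= 0, dt_inf <= 100, k >= 0, lag >= 0)
  set.seed(seed)
  clean <- (dt_inf / 100) * thod * conc *
    (1 - exp(-k * pmax(times - lag, 0)))
  noisy <- clean + blank_level + stats::rnorm(length(times), sd = noise_sd)
  series <- bod_series(sample_id, times, noisy,
                       blank_bod = rep(blank_level, length(times)),
                       conc = conc)
  truth <- data.frame(times = times,
                      dt = 100 * clean / (thod * conc))
  list(series = series, truth = truth,
       config = list(dt_inf = dt_inf, k = k, lag = lag,
                     blank_level = blank_level, noise_sd = noise_sd,
                     thod = thod, conc = conc, seed = seed))
}

#' Synthetic Flory-type oligomer peak list
#'
#' Emulates an electrospray spectrum of a step-growth condensation mixture:
#' chain lengths follow the most-probable (Flory) distribution at extent of
#' reaction `p`, truncated at `n_max`. Abundances are the weight fraction
#' `n p^(n-1) (1-p)^2` (or the number fraction `(1-p) p^(n-1)`), optionally
#' perturbed multiplicatively. Peak positions are `n * repeat_mass +
#' end_mass + adduct_mass`. The truncated-distribution Mn/Mw truth is
#' computed by direct summation, independent of [mass_summary()].
#'
#' @param p extent of reaction, in `[0, 1)`.
#' @param repeat_mass mass added per chain unit, g/mol.
#' @param end_mass mass of the chain ends (e.g. one water for a free
#'   acid/ol condensate), g/mol.
#' @param adduct_mass adduct mass added to each observed m/z.
#' @param n_max truncation chain length, at least 2.
#' @param abundance_mode `"weight"` or `"number"` fraction abundances.
#' @param abundance_noise multiplicative noise sd (0 = exact).
#' @param seed RNG seed.
#' @return List: `peaks` (a [peak_list()]), `truth` (`Mn`, `Mw`,
#'   `dispersity` of the truncated distribution), `config`.
#' @export
gen_flory_peaklist <- function(p = 0.5, repeat_mass = 200,
                               end_mass = 18.015,
                               adduct_mass = condensation_masses()["Na"],
                               n_max = 30L, abundance_mode = c("weight",
                                                               "number"),
                               abundance_noise = 0, seed = 1L) {
  abundance_mode <- match.arg(abundance_mode)
  stopifnot(p >= 0, p < 1, n_max >= 2L)
  set.seed(seed)
  n <- seq_len(n_max)
  number_frac <- (1 - p) * p^(n - 1)
  weight_frac <- n * p^(n - 1) * (1 - p)^2
  mass <- n * repeat_mass + end_mass
  ab <- if (abundance_mode == "weight") weight_frac else number_frac
  if (abundance_noise > 0) {
    ab <- ab * pmax(1 + stats::rnorm(n_max, sd = abundance_noise), 0)
  }
  # truth from the truncated distribution itself (number-weighted sums)
  w <- if (abundance_mode == "weight") weight_frac else number_frac
  mn_true <- sum(w * mass) / sum(w)
  mw_true <- sum(w * mass^2) / sum(w * mass)
  list(peaks = peak_list(mass + adduct_mass, ab),
       truth = list(Mn = mn_true, Mw = mw_true,
                    dispersity = mw_true / mn_true),
       config = list(p = p, repeat_mass = repeat_mass, end_mass = end_mass,
                     adduct_mass = unname(adduct_mass), n_max = n_max,
                     abundance_mode = abundance_mode,
                     abundance_noise = abundance_noise, seed = seed))
}

#' Random small-molecule SMILES generator
#'
#' Draws simple organic molecules (short alkyl/ether/alcohol/acid/amine
#' assemblies, 2-9 heavy atoms) for property-based testing of the descriptor
#' engine. Deterministic per seed.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @return Character vector of SMILES.
#' @export
gen_random_smiles <- function(n, seed = 1L) {
  set.seed(seed)
  backbones <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CCCCCC",
                 "c1ccccc1", "C1CCCCC1", "CCOCC", "CCCOC")
  substituents <- c("", "O", "N", "C(=O)O", "C(=O)C", "OC", "C#N", "Cl")
  vapply(seq_len(n), function(i) {
    bb <- sample(backbones, 1)
    sub <- sample(substituents, 1, prob = c(4, rep(1, 7)))
    paste0(bb, sub)
  }, character(1))
}
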