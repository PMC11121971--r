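#' Theoretical oxygen demand from an elemental formula
#'
#' Complete-oxidation stoichiometry with the ammonia rule for nitrogen:
#' a CcHhOoNn substance demands `c + h/4 - o/2 - 3n/4` moles of O2 per mole,
#' i.e. `32 * molO2 / MW` mg O2 per mg substance. Negative demand (already
#' fully oxidized) clamps to zero.
#'
#' @param formula formula string over C, H, O, N.
#' @return A `thod_spec` list: `value` (mg O2 / mg), `source = "formula"`.
#' @export
#' @examples
#' thod_from_formula("C3H8O3") # glycerol, 1.216 mg/mg
thod_from_formula <- function(formula) {
  counts <- parse_formula(formula)
  extra <- setdiff(names(counts), c("C", "H", "O", "N"))
  if (length(extra)) {
    stop("ThOD stoichiometry handles CHON only; found: ",
         paste(extra, collapse = ", "))
  }
  g <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  mol_o2 <- g("C") + g("H") / 4 - g("O") / 2 - 3 * g("N") / 4
  value <- max(0, 32 * mol_o2 / formula_mass(formula))
  structure(list(value = value, source = "formula"), class = "thod_spec")
}

#' @rdname thod_from_formula
#' @param value a known ThOD value in mg O2 per mg substance (e.g. taken
#'   from a published table). Table values and stoichiometric values can
#'   disagree; the package never silently substitutes one for the other.
#' @export
thod_value <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = value, source = "user"), class = "thod_spec")
}

#' Respirometric oxygen-demand series
#'
#' A biochemical oxygen demand (BOD) time course for one sample in a
#' closed-bottle seawater test, optionally with a parallel blank (inoculum
#' only) series on the same time grid.
#'
#' @param sample_id sample label.
#' @param times measurement times, days, strictly increasing.
#' @param bod BOD at each time, mg/L (negative readings clamp to 0).
#' @param blank_bod optional blank BOD, mg/L, same time grid.
#' @param conc test-substance concentration, mg/L.
#' @return A `bod_series` list.
#' @export
bod_series <- function(sample_id, times, bod, blank_bod = NULL, conc = 100) {
  stopifnot(length(times) == length(bod), conc > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(blank_bod) && length(blank_bod) != length(times)) {
    stop("blank series must share the sample time grid")
  }
  structure(list(sample_id = sample_id, times = as.numeric(times),
                 bod = pmax(as.numeric(bod), 0),
                 blank_bod = if (is.null(blank_bod)) NULL else
                   pmax(as.numeric(blank_bod), 0),
                 conc = conc),
            class = "bod_series")
}

#' Blank-correct a BOD series
#'
#' Subtracts the blank (control) oxygen demand pointwise, clamping at zero,
#' as when sample data are normalized against inoculum-only controls.
#'
#' @param series a [bod_series()] carrying a blank, or `blank` supplied
#'   separately.
#' @param blank optional blank values overriding the stored ones.
#' @return The corrected `bod_series` (blank removed).
#' @export
blank_correct <- function(series, blank = NULL) {
  stopifnot(inherits(series, "bod_series"))
  if (is.null(blank)) blank <- series$blank_bod
  if (is.null(blank)) stop("no blank series available")
  if (length(blank) != length(series$times)) {
    stop("blank series must share the sample time grid")
  }
  series$bod <- pmax(series$bod - pmax(blank, 0), 0)
  series$blank_bod <- NULL
  series
}

#' Degradation degree time course
#'
#' `Dt(t) = 100 * BOD(t) / (ThOD * conc)`: oxygen consumed relative to the
#' theoretical demand of the dosed substance, in percent. The day-5/10/21
#' milestones are read at the nearest recorded time; a milestone further
#' than `day_tol` days from any record is reported as `NA` with a warning.
#'
#' @param series a [bod_series()].
#' @param thod a `thod_spec` ([thod_from_formula()] or [thod_value()]).
#' @param milestones days at which headline Dt values are read.
#' @param day_tol maximum distance (days) for milestone matching.
#' @return A `biodegradation_result` list: `sample_id`, `times`, `dt_curve`
#'   (%), and `dt5`, `dt10`, `dt21`.
#' @export
degradation_degree <- function(series, thod, milestones = c(5, 10, 21),
                               day_tol = 1) {
  stopifnot(inherits(series, "bod_series"), inherits(thod, "thod_spec"))
  if (thod$value <= 0) stop("ThOD must be positive")
  dt <- 100 * series$bod / (thod$value * series$conc)
  ms <- vapply(milestones, function(d) {
    i <- which.min(abs(series$times - d))
    if (abs(series$times[i] - d) > day_tol) {
      warning("no record within ", day_tol, " day(s) of day ", d,
              " for ", series$sample_id)
      return(NA_real_)
    }
    dt[i]
  }, numeric(1))
  names(ms) <- paste0("dt", milestones)
  structure(c(list(sample_id = series$sample_id, times = series$times,
                   dt_curve = dt), as.list(ms)),
            class = "biodegradation_result")
}

#' @export
print.biodegradation_result <- function(x, ...) {
  cat("<biodegradation_result> ", x$sample_id,
      sprintf(": Dt5 %.2f%%, Dt10 %.2f%%, Dt21 %.2f%%\n",
              x$dt5, x$dt10, x$dt21), sep = "")
  invisible(x)
}

#' Summarize a batch of degradation results
#'
#' @param results list of `biodegradation_result`s.
#' @param inoculum optional inoculum labels, recycled to the batch.
#' @return Long-form data.frame: `sample`, `inoculum`, `dt5`, `dt10`, `dt21`.
#' @export
summarize_batch <- function(results, inoculum = NA_character_) {
  if (!length(results)) stop("no results to summarize")
  stopifnot(all(vapply(results, inherits, logical(1),
                       "biodegradation_result")))
  data.frame(
    sample = vapply(results, `[[`, character(1), "sample_id"),
    inoculum = rep_len(inoculum, length(results)),
    dt5 = vapply(results, `[[`, numeric(1), "dt5"),
    dt10 = vapply(results, `[[`, numeric(1), "dt10"),
    dt21 = vapply(results, `[[`, numeric(1), "dt21"),
    stringsAsFactors = FALSE
  )
}

#' Batch degradation arithmetic from a CSV table
#'
#' Reads a respirometry table (`sample_id`, `time_d`, `bod_mg_L`, optional
#' `blank_mg_L`, `conc_mg_L`, `thod_mg_mg`) and returns the Dt summary.
#'
#' @param path input CSV.
#' @return data.frame as from [summarize_batch()].
#' @export
biodeg_from_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_d", "bod_mg_L", "conc_mg_L", "thod_mg_mg")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  res <- lapply(split(tab, tab$sample_id), function(d) {
    d <- d[order(d$time_d), ]
    s <- bod_series(d$sample_id[1], d$time_d, d$bod_mg_L,
                    blank_bod = if ("blank_mg_L" %in% names(d))
                      d$blank_mg_L else NULL,
                    conc = d$conc_mg_L[1])
    if (!is.null(s$blank_bod)) s <- blank_correct(s)
    degradation_degree(s, thod_value(d$thod_mg_mg[1]))
  })
  summarize_batch(unname(res))
}
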