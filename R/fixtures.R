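#' Load the packaged reference tables
#'
#' Returns the in-package reference fixtures used by the reproduction
#' pipeline: oligoester Mn/Mw/dispersity records (`table1`), the co- and
#' ter-oligomer respirometry table (`table2`), the monomer respirometry
#' table with two inocula (`table4`), the oligoamide table (`table5`,
#' no ThOD printed), the twelve tetramer model structures with their
#' biodegradation responses (`table6`), plus the selected descriptor names
#' and the ADME exclusion list.
#'
#' @return Named list of data.frames and name vectors.
#' @export
load_fixtures <- function() {
  p <- function(f) system.file("extdata", f, package = "oligodeg")
  fx <- list(
    table1 = utils::read.csv(p("table1_mass_summary.csv"),
                             stringsAsFactors = FALSE),
    table2 = utils::read.csv(p("table2_cooligomer_bod.csv"),
                             stringsAsFactors = FALSE),
    table4 = utils::read.csv(p("table4_monomer_bod.csv"),
                             stringsAsFactors = FALSE),
    table5 = utils::read.csv(p("table5_oligoamide_bod.csv"),
                             stringsAsFactors = FALSE),
    table6 = utils::read.csv(p("table6_tetramers.csv"),
                             stringsAsFactors = FALSE),
    selected18 = selected_descriptor_names(),
    adme_exclusions = adme_exclusion_names()
  )
  stopifnot(nrow(fx$table6) == 12L, length(fx$selected18) == 18L)
  fx
}

#' Recompute every derivable fixture cell and flag discrepancies
#'
#' Recomputes each degradation-degree cell as `100 * BOD / (ThOD * conc)`
#' at the standard 100 mg/L test concentration, and each dispersity as
#' `floor(Mw/Mn, 2dp)`, then compares with the printed value. Status is
#' `match` within `tol`, `known_discrepancy` for cells on the curated list
#' of internal inconsistencies of the source tables, and `mismatch`
#' otherwise. The oligoamide table prints no ThOD, so its Dt cells are
#' reported `not_derivable`.
#'
#' @param fixtures from [load_fixtures()].
#' @param conc assumed test concentration, mg/L.
#' @param tol absolute agreement tolerance on a Dt cell (%), matching the
#'   rounding of the printed tables.
#' @param tol_disp agreement tolerance on a dispersity cell (printed at two
#'   decimals, so half a unit in the last place).
#' @return data.frame: `table`, `sample`, `cell`, `printed`, `recomputed`,
#'   `status`.
#' @export
verify_fixture_consistency <- function(fixtures = load_fixtures(),
                                       conc = 100, tol = 0.02,
                                       tol_disp = 0.005) {
  if (!length(fixtures) || is.null(fixtures$table2)) {
    stop("empty or incomplete fixture set")
  }
  known <- known_discrepancies()
  rows <- list()
  add <- function(tab, sample, cell, printed, recomputed, derivable = TRUE) {
    cell_tol <- if (cell == "dispersity") tol_disp else tol
    status <- if (!derivable) "not_derivable"
    else if (is.finite(printed) && abs(printed - recomputed) <= cell_tol)
      "match"
    else if (any(known$table == tab & known$sample == sample &
                 known$cell == cell)) "known_discrepancy"
    else "mismatch"
    rows[[length(rows) + 1L]] <<- data.frame(
      table = tab, sample = sample, cell = cell, printed = printed,
      recomputed = recomputed, status = status, stringsAsFactors = FALSE)
  }
  dt_cells <- function(tab_name, tab, key) {
    for (i in seq_len(nrow(tab))) {
      for (day in c(5, 10, 21)) {
        bod <- tab[[paste0("bod", day)]][i]
        printed <- tab[[paste0("dt", day)]][i]
        thod <- tab$thod[i]
        rec <- if (is.finite(thod)) 100 * bod / (thod * conc) else NA_real_
        add(tab_name, key(tab, i), paste0("dt", day), printed, rec,
            derivable = is.finite(thod))
      }
    }
  }
  dt_cells("table2", fixtures$table2, function(t, i) t$sample[i])
  dt_cells("table4", fixtures$table4,
           function(t, i) paste(t$sample[i], t$inoculum[i], sep = "/"))
  dt_cells("table5", fixtures$table5, function(t, i) t$sample[i])
  t1 <- fixtures$table1
  for (i in seq_len(nrow(t1))) {
    add("table1", t1$sample[i], "dispersity", t1$dispersity[i],
        floor_dispersity(t1$mw[i] / t1$mn[i]))
  }
  do.call(rbind, rows)
}

#' Curated list of internal inconsistencies of the reference tables
#'
#' Cells whose printed value cannot be recomputed from the other printed
#' values of the same source (cross-table disagreements and rounding
#' anomalies), kept explicit so every remaining mismatch is a real error.
#'
#' @return data.frame: `table`, `sample`, `cell`.
#' @export
known_discrepancies <- function() {
  rows <- rbind(
    c("table2", "BDO-AA", "dt10"),
    c("table2", "BDO-AA", "dt21"),     # 50.23 by arithmetic; table prints 49.95
    c("table2", "GLY-TA", "dt10"),
    c("table2", "GLY-TA", "dt21"),     # 50.12 by arithmetic; table prints 50.23
    c("table4", "FDCA/Trieste", "dt10"),
    c("table4", "FDCA/Trieste", "dt21"),
    c("table4", "FDCA/Zaule", "dt21"),
    c("table4", "TA/Trieste", "dt10"),
    c("table4", "TA/Trieste", "dt21"),
    c("table4", "AA/Trieste", "dt21"),
    c("table4", "BDO/Trieste", "dt21"),
    c("table4", "GLY/Trieste", "dt21"),
    c("table4", "ERY/Trieste", "dt10"),
    c("table4", "ERY/Trieste", "dt21"),
    c("table4", "DMT/Trieste", "dt10"),
    c("table4", "DMT/Trieste", "dt21"),
    c("table4", "DMF/Trieste", "dt10"),
    c("table4", "DMF/Trieste", "dt21"),
    c("table1", "GLY-FDCA-AA", "dispersity"), # 551/481 = 1.15, prints 1.25
    c("table1", "GLY-ERY-AA", "dispersity")   # 1140/845 = 1.34, prints 1.35
  )
  data.frame(table = rows[, 1], sample = rows[, 2], cell = rows[, 3],
             stringsAsFactors = FALSE)
}

#' Map a tetramer label to its monomer sequence
#' @param label e.g. `"BDO-FDCA-BDO-AA"`.
#' @return Character vector of monomer ids.
#' @export
label_to_sequence <- function(label) {
  strsplit(label, "-", fixed = TRUE)[[1]]
}

#' Match a labelled tetramer against a recorded structure
#'
#' Builds the tetramer from the label order and compares it canonically
#' with the recorded SMILES; when the label order does not reproduce the
#' structure, every alternation-preserving reordering of the same unit
#' multiset is tried (labels occasionally disagree with the drawn chain
#' orientation). Equality is always structural, never string-based.
#'
#' @param label tetramer label, units separated by `-`.
#' @param printed_smiles the recorded SMILES string.
#' @return List: `match_type` (`"label_order"`, `"reordered"`, `"none"`),
#'   `sequence` (the matching unit order, or the label order when none
#'   matches) and `built_smiles`.
#' @export
match_tetramer_structure <- function(label, printed_smiles) {
  units <- label_to_sequence(label)
  built <- build_oligomer(units)
  if (structures_equal(built$smiles, printed_smiles)) {
    return(list(match_type = "label_order", sequence = units,
                built_smiles = built$smiles))
  }
  acyl <- is_acyl_monomer(units)
  acids <- units[acyl]
  ols <- units[!acyl]
  orders <- list()
  for (a in list(acids, rev(acids))) {
    for (o in list(ols, rev(ols))) {
      orders <- c(orders,
                  list(c(a[1], o[1], a[2], o[2]),   # acid-first chain
                       c(o[1], a[1], o[2], a[2])))  # ol-first chain
    }
  }
  for (units2 in unique(orders)) {
    b2 <- build_oligomer(units2)
    if (structures_equal(b2$smiles, printed_smiles)) {
      return(list(match_type = "reordered", sequence = units2,
                  built_smiles = b2$smiles))
    }
  }
  list(match_type = "none", sequence = units, built_smiles = built$smiles)
}
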