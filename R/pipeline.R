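#' Configuration of the reproduction pipeline
#'
#' @param seed master seed for embedding, clustering and any simulation.
#' @param mif a [mif_config()].
#' @param n_lv PLS latent variables.
#' @param n_comp PCA components retained for plotting/clustering.
#' @param k clusters requested from K-means on the PCA scores (two clusters
#'   plus a singleton outlier group).
#' @param exclude_ids molecule labels excluded from the PLS stage (the
#'   nitrogen-containing tetramer is the score-space outlier).
#' @param scale scaling convention for PCA and PLS.
#' @return A named list.
#' @export
reproduction_config <- function(seed = 20240516L,
                                mif = mif_config(),
                                n_lv = 5L, n_comp = 2L, k = 3L,
                                exclude_ids = "AA-DAF-AA-DAF",
                                scale = "autoscale") {
  list(seed = seed, mif = mif, n_lv = n_lv, n_comp = n_comp, k = k,
       exclude_ids = exclude_ids, scale = scale)
}

#' Run the end-to-end structure/biodegradability reproduction
#'
#' Executes the whole screening workflow on the packaged reference tables:
#' (1) builds the twelve tetramer model structures from their labels and
#' verifies them against the recorded SMILES; (2) computes the
#' 18-descriptor MIF matrix from seeded conformers; (3) fits a PCA and
#' K-means clustering on the scores; (4) fits the PLS regression of the
#' biodegradation response at `n_lv` latent variables with leave-one-out
#' Q2, both without the excluded outlier (primary) and on all twelve
#' structures (variant); (5) re-verifies the respirometry and dispersity
#' arithmetic of the reference tables.
#'
#' @param config from [reproduction_config()].
#' @param verbose print per-stage progress.
#' @return A `run_report` list; see the fields referenced above.
#' @export
run_paper_reproduction <- function(config = reproduction_config(),
                                   verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  fx <- load_fixtures()
  t6 <- fx$table6

  say("stage 1/5: building tetramer model structures")
  matched <- lapply(seq_len(nrow(t6)), function(i) {
    match_tetramer_structure(t6$label[i], t6$smiles[i])
  })
  structures <- data.frame(label = t6$label,
                           built_smiles = vapply(matched, `[[`,
                                                 character(1),
                                                 "built_smiles"),
                           printed_smiles = t6$smiles,
                           match_type = vapply(matched, `[[`, character(1),
                                               "match_type"),
                           canonical_match = vapply(matched, function(m)
                             m$match_type != "none", logical(1)),
                           biodeg = t6$biodeg,
                           stringsAsFactors = FALSE)
  matches <- structures$canonical_match

  say("stage 2/5: computing MIF descriptor matrix (", nrow(t6),
      " molecules)")
  X <- descriptor_matrix(t6$smiles, ids = t6$label, config = config$mif,
                         seed = config$seed)
  pre <- pretreat(X, exclude = fx$adme_exclusions)

  say("stage 3/5: PCA and K-means clustering")
  pca <- pca_fit(pre$X, n_comp = config$n_comp, scale = config$scale)
  km <- kmeans_cluster(pca$scores, k = config$k, seed = config$seed)
  sizes <- table(km$labels)
  outlier_label <- names(km$labels)[km$labels %in%
                                      as.integer(names(sizes)[sizes == 1])]

  say("stage 4/5: PLS regression with leave-one-out Q2")
  keep <- !(rownames(pre$X) %in% config$exclude_ids)
  fit_set <- function(rows) {
    # re-prune: a column can lose all variance on the subset (e.g. the
    # acidity rule value once the single amide structure is excluded)
    Xs <- pretreat(pre$X[rows, , drop = FALSE], exclude = character(0))$X
    ys <- t6$biodeg[match(rownames(Xs), t6$label)]
    n_lv <- min(config$n_lv, qr(scale_matrix(Xs, config$scale)$X)$rank)
    fit <- pls_fit(Xs, ys, n_lv = n_lv, scale = config$scale)
    cv <- loo_q2(Xs, ys, n_lv = n_lv, scale = config$scale)
    list(n = nrow(Xs), n_lv = n_lv, R2 = fit$R2, Q2 = cv$Q2,
         PRESS = cv$PRESS, coefficients = fit$coefficients,
         fitted = stats::setNames(fit$fitted, rownames(Xs)))
  }
  pls_primary <- fit_set(keep)
  pls_all <- fit_set(rep(TRUE, nrow(pre$X)))

  say("stage 5/5: reference-table arithmetic verification")
  consistency <- verify_fixture_consistency(fx)

  structure(list(
    config = config,
    structures = structures,
    n_structures_matched = sum(matches),
    descriptors = X,
    pretreat_report = pre$report,
    pca = pca,
    clusters = km,
    cluster_sizes = as.integer(sizes),
    outlier_label = outlier_label,
    pls = pls_primary,
    pls_all12 = pls_all,
    consistency = consistency,
    session = list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("oligodeg")))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  structures: ", x$n_structures_matched, "/",
      nrow(x$structures), " canonical matches to the recorded SMILES\n",
      sep = "")
  cat("  PCA explained %: ",
      paste(sprintf("%.1f", utils::head(x$pca$explained_pct, 3)),
            collapse = ", "), "\n", sep = "")
  cat("  K-means (k=", x$clusters$k, ") cluster sizes: ",
      paste(sort(x$cluster_sizes, decreasing = TRUE), collapse = "/"),
      if (length(x$outlier_label))
        paste0("; singleton: ", paste(x$outlier_label, collapse = ", ")),
      "\n", sep = "")
  cat(sprintf("  PLS (n=%d, %d LV): R2 = %.3f, Q2 = %.3f\n",
              x$pls$n, x$pls$n_lv, x$pls$R2, x$pls$Q2))
  cat(sprintf("  PLS all-12 variant: R2 = %.3f, Q2 = %.3f\n",
              x$pls_all12$R2, x$pls_all12$Q2))
  tab <- table(x$consistency$status)
  cat("  table arithmetic: ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a run report to a directory
#'
#' Emits the descriptor matrix and consistency table as CSV and the model
#' summaries as JSON; regenerable byte-identically from the same config and
#' seed.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_descriptor_csv(report$descriptors,
                       file.path(dir, "descriptors.csv"))
  utils::write.csv(report$consistency,
                   file.path(dir, "table_consistency.csv"),
                   row.names = FALSE)
  utils::write.csv(report$structures, file.path(dir, "structures.csv"),
                   row.names = FALSE)
  summary <- list(
    seed = report$session$seed,
    pca_explained_pct = report$pca$explained_pct,
    cluster_labels = as.list(report$clusters$labels),
    pls = report$pls[c("n", "n_lv", "R2", "Q2", "PRESS")],
    pls_coefficients = as.list(report$pls$coefficients),
    pls_all12 = report$pls_all12[c("n", "n_lv", "R2", "Q2", "PRESS")],
    n_structures_matched = report$n_structures_matched
  )
  jsonlite::write_json(summary, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
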