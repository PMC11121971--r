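#' Default ADME descriptor exclusion list
#'
#' Descriptor names designed for drug absorption/distribution modelling that
#' are dropped during pretreatment of a full descriptor matrix: intestinal
#' absorption (CACO2), metabolic stability (MetStab), protein binding (PB),
#' volume of distribution (VD), blood-brain permeability (LgBB) and skin
#' permeability (SKIN).
#' @return Character vector.
#' @export
adme_exclusion_names <- function() {
  c("CACO2", "MetStab", "PB", "VD", "LgBB", "SKIN")
}

#' Pretreat a descriptor matrix
#'
#' Drops zero-variance columns (variance at or below `var_tol`) and columns
#' named in `exclude`, and reports what was removed.
#'
#' @param X numeric matrix (molecules x descriptors) with column names.
#' @param exclude column names to drop regardless of variance.
#' @param var_tol variance threshold for the zero-variance rule.
#' @return List with the pruned matrix `X` and a `report` containing
#'   `dropped_zero_variance`, `dropped_excluded` and `kept`.
#' @export
pretreat <- function(X, exclude = adme_exclusion_names(), var_tol = 1e-12) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("pretreatment needs at least two rows")
  if (is.null(colnames(X))) stop("X must have column names")
  vars <- apply(X, 2, stats::var)
  zero_var <- colnames(X)[vars <= var_tol | !is.finite(vars)]
  excluded <- intersect(exclude, colnames(X))
  drop <- union(zero_var, excluded)
  keep <- setdiff(colnames(X), drop)
  if (!length(keep)) stop("pretreatment dropped every column")
  list(X = X[, keep, drop = FALSE],
       report = list(dropped_zero_variance = zero_var,
                     dropped_excluded = excluded,
                     kept = length(keep)))
}

# shared scaling for PCA / PLS: autoscale (centre + unit variance) or centre
scale_matrix <- function(X, scale = c("autoscale", "center_only")) {
  scale <- match.arg(scale)
  mx <- colMeans(X)
  sx <- if (scale == "autoscale") apply(X, 2, stats::sd) else
    rep(1, ncol(X))
  # a column that is constant (possibly only within this fold) is inert
  # after centering; unit scale keeps it from producing NaN
  sx[sx == 0 | !is.finite(sx)] <- 1
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  list(X = Xs, center = mx, scale = sx)
}

#' Principal component analysis of a descriptor matrix
#'
#' PCA by singular-value decomposition of the scaled matrix. The explained
#' percentage per component comes from the squared singular values. The sign
#' of each component is fixed by forcing its largest-magnitude loading
#' positive, so score plots are reproducible.
#'
#' @param X numeric matrix with column names.
#' @param n_comp number of components to keep.
#' @param scale `"autoscale"` (default) or `"center_only"`.
#' @return A `pca_model` list: `loadings` (p x n_comp), `scores`
#'   (n x n_comp), `explained_pct` (all min(n-1, p) components), `scale`.
#' @export
pca_fit <- function(X, n_comp = 2L, scale = c("autoscale", "center_only")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  maxc <- min(nrow(X) - 1L, ncol(X))
  if (n_comp < 1L || n_comp > maxc) {
    stop("n_comp must be between 1 and min(rows - 1, cols) = ", maxc)
  }
  sc <- scale_matrix(X, scale)
  sv <- svd(sc$X)
  explained <- 100 * sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(n_comp), drop = FALSE]
  scores <- sc$X %*% loadings
  flip <- vapply(seq_len(n_comp), function(k) {
    sign(loadings[which.max(abs(loadings[, k])), k])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(n_comp)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_comp)))
  structure(list(loadings = loadings, scores = scores,
                 explained_pct = explained[seq_len(maxc)],
                 scale = scale),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- ncol(x$scores)
  cat("<pca_model> ", k, " components; explained %: ",
      paste(sprintf("%.1f", x$explained_pct[seq_len(min(3, length(x$explained_pct)))]),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' K-means clustering of score-space points
#'
#' Best-of-`n_init` Lloyd iterations, deterministic for a fixed seed.
#'
#' @param scores numeric matrix of points (e.g. PCA scores).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_init random restarts.
#' @return A `cluster_result` list: `k`, `labels` (0-based, named by row),
#'   `seed`, `inertia` (total within-cluster sum of squares), `centers`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1L, n_init = 25L) {
  scores <- as.matrix(scores)
  if (k < 1L) stop("k must be at least 1")
  if (k > nrow(scores)) stop("k cannot exceed the number of points")
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_init,
                      iter.max = 100L, algorithm = "Lloyd")
  labels <- km$cluster - 1L
  names(labels) <- rownames(scores)
  structure(list(k = k, labels = labels, seed = seed,
                 inertia = km$tot.withinss, centers = km$centers),
            class = "cluster_result")
}

#' Partial least squares regression (NIPALS)
#'
#' Single-response PLS1 by the NIPALS latent-variable decomposition on the
#' scaled matrix, with coefficients back-transformed to the original
#' descriptor scale.
#'
#' @param X numeric matrix (n x p) with column names.
#' @param y numeric response, length n.
#' @param n_lv number of latent variables.
#' @param scale `"autoscale"` or `"center_only"` applied to X; y is centred.
#' @return A `pls_model` list: `n_lv`, `coefficients` (original scale, named),
#'   `intercept`, `fitted`, `R2`, `scores`, `loadings`, `weights`, plus the
#'   scaling constants needed by [predict.pls_model()].
#' @export
pls_fit <- function(X, y, n_lv, scale = c("autoscale", "center_only")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response: TSS is zero")
  rk <- qr(scale_matrix(X, scale)$X)$rank
  if (n_lv < 1L || n_lv > rk) {
    stop("n_lv must be between 1 and rank(X) = ", rk)
  }
  sc <- scale_matrix(X, scale)
  E <- sc$X
  f <- y - mean(y)
  p <- ncol(X)
  Wm <- matrix(0, p, n_lv)
  Pm <- matrix(0, p, n_lv)
  Tm <- matrix(0, nrow(X), n_lv)
  qv <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (a == 1L && nw < 1e-12) stop("X carries no covariance with y")
    if (nw < 1e-12) { # response fully deflated
      Wm <- Wm[, seq_len(a - 1L), drop = FALSE]
      Pm <- Pm[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]
      qv <- qv[seq_len(a - 1L)]
      n_lv <- a - 1L
      break
    }
    w <- w / nw
    tvec <- drop(E %*% w)
    tt <- sum(tvec^2)
    pvec <- drop(crossprod(E, tvec)) / tt
    qa <- sum(f * tvec) / tt
    E <- E - tcrossprod(tvec, pvec)
    f <- f - qa * tvec
    Wm[, a] <- w; Pm[, a] <- pvec; Tm[, a] <- tvec; qv[a] <- qa
  }
  # B = W (P'W)^-1 q, on the scaled X; back-transform to original units
  Bs <- drop(Wm %*% solve(crossprod(Pm, Wm), qv))
  coefficients <- Bs / sc$scale
  names(coefficients) <- colnames(X)
  intercept <- mean(y) - sum(coefficients * sc$center)
  fitted <- drop(X %*% coefficients) + intercept
  R2 <- 1 - sum((y - fitted)^2) / tss
  structure(list(n_lv = n_lv, coefficients = coefficients,
                 intercept = intercept, fitted = fitted, R2 = R2,
                 scores = Tm, loadings = Pm, weights = Wm,
                 y_mean = mean(y), x_center = sc$center,
                 x_scale = sc$scale, scale = scale),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_lv, " latent variables, R2 = ",
      sprintf("%.4f", x$R2), "\n", sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated Q2
#'
#' For each observation the model (including the scaling) is refit without
#' it and the held-out response predicted; `Q2 = 1 - PRESS / TSS`. Q2 can be
#' negative and is reported as computed.
#'
#' @inheritParams pls_fit
#' @return List with `Q2` and `PRESS`.
#' @export
loo_q2 <- function(X, y, n_lv, scale = c("autoscale", "center_only")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 observations")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response: TSS is zero")
  press <- 0
  for (i in seq_len(n)) {
    fit <- pls_fit(X[-i, , drop = FALSE], y[-i], n_lv = n_lv, scale = scale)
    pred <- predict(fit, X[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  list(Q2 = 1 - press / tss, PRESS = unname(press))
}

#' Feature selection for the PLS stage
#'
#' Two modes: `explicit_list` returns the supplied descriptor names after
#' checking they exist (the packaged reproduction path uses the 18 selected
#' descriptors), and `forward_q2` greedily adds the variable that most
#' improves the leave-one-out Q2 until no candidate improves it by more
#' than `tol`.
#'
#' @param X numeric matrix with column names.
#' @param y response (required for `forward_q2`).
#' @param mode `"explicit_list"` or `"forward_q2"`.
#' @param features names for `explicit_list` (default: the packaged 18).
#' @param n_lv latent variables used when scoring candidates (capped at the
#'   current subset size).
#' @param tol minimum Q2 improvement to continue; the default demands a
#'   practically meaningful gain, which keeps chance improvements from
#'   noise variables out of the subset.
#' @param scale scaling passed through to the PLS fits.
#' @return Character vector of selected column names.
#' @export
select_features <- function(X, y = NULL,
                            mode = c("explicit_list", "forward_q2"),
                            features = selected_descriptor_names(),
                            n_lv = 2L, tol = 0.01,
                            scale = c("autoscale", "center_only")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (mode == "explicit_list") {
    missing <- setdiff(features, colnames(X))
    if (length(missing)) {
      stop("feature(s) absent from X: ", paste(missing, collapse = ", "))
    }
    return(features)
  }
  if (is.null(y)) stop("forward_q2 selection needs a response")
  chosen <- character(0)
  best_q2 <- -Inf
  pool <- colnames(X)
  repeat {
    q2s <- vapply(setdiff(pool, chosen), function(f) {
      cols <- c(chosen, f)
      lv <- min(n_lv, length(cols))
      out <- try(loo_q2(X[, cols, drop = FALSE], y, n_lv = lv,
                        scale = scale), silent = TRUE)
      if (inherits(out, "try-error")) -Inf else out$Q2
    }, numeric(1))
    if (!length(q2s) || max(q2s) <= best_q2 + tol) break
    chosen <- c(chosen, names(which.max(q2s)))
    best_q2 <- max(q2s)
  }
  chosen
}
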