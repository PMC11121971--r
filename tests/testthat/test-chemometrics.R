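test_that("pretreatment drops zero-variance and excluded columns", {
  set.seed(1)
  X <- matrix(rnorm(10 * 126), 10)
  colnames(X) <- paste0("D", 1:126)
  X[, 1:9] <- matrix(rep(runif(9), each = 10), 10) # 9 constants
  colnames(X)[100:105] <- adme_exclusion_names()   # 6 excluded, disjoint
  out <- pretreat(X)
  expect_equal(out$report$kept, 111L)
  expect_length(out$report$dropped_zero_variance, 9L)
  expect_length(out$report$dropped_excluded, 6L)
  expect_equal(ncol(out$X), 111L)

  # no constants and no exclusions: identity
  X2 <- matrix(rnorm(20), 5); colnames(X2) <- paste0("a", 1:4)
  expect_equal(pretreat(X2, exclude = character(0))$X, X2)

  # degenerate input
  Xc <- matrix(1, 5, 3); colnames(Xc) <- c("a", "b", "c")
  expect_error(pretreat(Xc), "every column")
  expect_error(pretreat(X[1, , drop = FALSE]), "two rows")
})

test_that("PCA explains variance in order and honours planted structure", {
  # rank-1 matrix: PC1 explains everything
  u <- rnorm(12); v <- rnorm(5)
  X1 <- outer(u, v); colnames(X1) <- paste0("c", 1:5)
  m1 <- pca_fit(X1, n_comp = 2, scale = "center_only")
  expect_equal(m1$explained_pct[1], 100, tolerance = 1e-8)

  set.seed(42)
  Xr <- matrix(rnorm(30 * 6), 30); colnames(Xr) <- paste0("c", 1:6)
  mr <- pca_fit(Xr, n_comp = 4)
  expect_true(all(diff(mr$explained_pct) <= 1e-9))
  expect_lte(sum(mr$explained_pct), 100 + 1e-6)
  # orthonormal loadings
  expect_equal(crossprod(mr$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)

  # planted two-factor model, factor variances 4:1, tiny noise
  set.seed(7)
  n <- 400
  f1 <- rnorm(n, sd = 2); f2 <- rnorm(n, sd = 1)
  v1 <- c(1, 0, 1, 0, 1, 0) / sqrt(3)
  v2 <- c(0, 1, 0, -1, 0, 1) / sqrt(3)
  Xp <- outer(f1, v1) + outer(f2, v2) +
    matrix(rnorm(n * 6, sd = 0.01), n)
  colnames(Xp) <- paste0("c", 1:6)
  mp <- pca_fit(Xp, n_comp = 2, scale = "center_only")
  ratio <- mp$explained_pct[1] / mp$explained_pct[2]
  expect_equal(ratio, 4, tolerance = 0.10)

  # scores invariant (up to sign) under row permutation
  perm <- sample(nrow(Xr))
  m_perm <- pca_fit(Xr[perm, ], n_comp = 2)
  expect_equal(abs(m_perm$scores), abs(mr$scores[perm, 1:2]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_fit(Xr, n_comp = 10), "n_comp")
})

test_that("k-means clustering recovers planted structure deterministically", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(20, 0, 0.5), 10),
               matrix(rnorm(20, 10, 0.5), 10),
               matrix(rnorm(20, -10, 0.5), 10))
  rownames(pts) <- paste0("p", 1:30)
  truth <- rep(0:2, each = 10)

  km1 <- kmeans_cluster(pts, k = 3, seed = 99)
  km2 <- kmeans_cluster(pts, k = 3, seed = 99)
  expect_identical(km1$labels, km2$labels)
  # label-invariant agreement with the planting
  expect_equal(length(unique(paste(km1$labels, truth))), 3L)

  kone <- kmeans_cluster(pts, k = 1, seed = 1)
  expect_true(all(kone$labels == 0))
  scatter <- sum(scale(pts, scale = FALSE)^2)
  expect_equal(kone$inertia, scatter, tolerance = 1e-8)

  kn <- kmeans_cluster(pts, k = nrow(pts), seed = 1)
  expect_equal(kn$inertia, 0)
  expect_error(kmeans_cluster(pts, k = 31), "exceed")
  expect_error(kmeans_cluster(pts, k = 0), "at least 1")
})

test_that("PLS reduces to exact and least-squares solutions", {
  # rank-1 X with y in its span: perfect fit at one latent variable
  u <- rnorm(15); v <- c(2, -1, 0.5)
  X1 <- outer(u, v); colnames(X1) <- paste0("x", 1:3)
  y1 <- drop(X1 %*% c(1, 1, 1))
  f1 <- pls_fit(X1, y1, n_lv = 1)
  expect_equal(f1$R2, 1, tolerance = 1e-10)

  # full rank, n > p: all-LV PLS equals ordinary least squares
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40); colnames(X) <- paste0("x", 1:5)
  y <- drop(X %*% c(1, -2, 0, 0.5, 3)) + rnorm(40, sd = 0.3)
  fit <- pls_fit(X, y, n_lv = 5)
  ols <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_lt(max(abs(fit$coefficients - ols[-1])), 1e-8)
  expect_lt(abs(fit$intercept - ols[1]), 1e-8)

  # orthogonal, centred X: the full PLS solution equals per-column
  # regression
  M <- scale(matrix(rnorm(30 * 4), 30), scale = FALSE)
  Q <- qr.Q(qr(M)) # combinations of centred columns stay centred
  colnames(Q) <- paste0("q", 1:4)
  yq <- drop(Q %*% c(1, 2, 3, 4)) + rnorm(30, sd = 0.1)
  fq <- pls_fit(Q, yq, n_lv = 4, scale = "center_only")
  percol <- vapply(1:4, function(j) {
    xc <- Q[, j] - mean(Q[, j])
    sum(xc * (yq - mean(yq))) / sum(xc^2)
  }, numeric(1))
  expect_equal(unname(fq$coefficients), percol, tolerance = 1e-8)

  expect_error(pls_fit(X, rep(1, 40), n_lv = 2), "constant|TSS")
  expect_error(pls_fit(X, y, n_lv = 9), "rank")
})

test_that("PLS recovers planted coefficients from noisy descriptor-like data", {
  # full-rank fit; coefficients compared on the standardized scale, the
  # scale-free convention for mixed-unit descriptor blocks
  d <- gen_pls_dataset(n_samples = 100, n_descriptors = 18,
                       n_informative = 5, noise_sd = 0.05, seed = 21)
  fit <- pls_fit(d$X, d$y, n_lv = 18)
  sx <- apply(d$X, 2, stats::sd)
  r <- stats::cor(fit$coefficients * sx, d$beta_true * sx)
  expect_gt(r, 0.95)
})

test_that("leave-one-out Q2 behaves like a cross-validated R2", {
  set.seed(12)
  X <- matrix(rnorm(60 * 4), 60); colnames(X) <- paste0("x", 1:4)
  y <- drop(X %*% c(1, 2, -1, 0.5))
  cv <- loo_q2(X, y, n_lv = 4)
  expect_gt(cv$Q2, 0.99)
  fit <- pls_fit(X, y, n_lv = 4)
  expect_lte(cv$Q2, fit$R2)

  # Q2 never exceeds R2 across random datasets
  for (s in 1:5) {
    d <- gen_pls_dataset(n_samples = 25, n_descriptors = 8,
                         n_informative = 3, noise_sd = 0.4, seed = s)
    lv <- 3
    expect_lte(loo_q2(d$X, d$y, n_lv = lv)$Q2,
               pls_fit(d$X, d$y, n_lv = lv)$R2 + 1e-10)
  }

  # permutation null: no predictivity once y is shuffled
  d <- gen_pls_dataset(n_samples = 30, n_descriptors = 10,
                       n_informative = 3, noise_sd = 0.1, seed = 5)
  set.seed(99)
  q2s <- vapply(1:50, function(i) {
    loo_q2(d$X, sample(d$y), n_lv = 3)$Q2
  }, numeric(1))
  expect_lte(stats::median(q2s), 0)

  expect_error(loo_q2(X[1:2, ], y[1:2], n_lv = 1), "at least 3")
})

test_that("feature selection validates explicit lists and finds planted pairs", {
  X <- matrix(rnorm(10 * 18), 10)
  colnames(X) <- selected_descriptor_names()
  expect_identical(select_features(X, mode = "explicit_list"),
                   selected_descriptor_names())
  expect_error(select_features(X, mode = "explicit_list",
                               features = c("IW1", "nope")), "absent")

  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    Xf <- matrix(rnorm(30 * 12), 30)
    colnames(Xf) <- paste0("v", 1:12)
    yf <- drop(Xf[, c(3, 7)] %*% c(2, -2)) + rnorm(30, sd = 0.1)
    sel <- select_features(Xf, yf, mode = "forward_q2", n_lv = 2)
    if (setequal(sel, c("v3", "v7"))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
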