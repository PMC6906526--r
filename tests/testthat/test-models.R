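test_that("PCA matches the dense eigendecomposition and its invariants", {
  set.seed(21)
  X <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], c("x", "y", "z")))
  m <- pca_fit(X)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(m$eigenvalues), ev[seq_along(m$eigenvalues)],
               tolerance = 1e-8)
  expect_equal(unname(var(m$scores[, 1])), unname(m$eigenvalues[1]),
               tolerance = 1e-8)
  expect_lt(abs(cov(m$scores[, 1], m$scores[, 2])), 1e-8)
  expect_equal(unname(crossprod(m$loadings)), diag(ncol(m$loadings)),
               tolerance = 1e-8)

  # data on a line: one component explains everything
  t <- rnorm(10)
  L <- outer(t, c(1, 2, 3))
  colnames(L) <- c("x", "y", "z"); rownames(L) <- sprintf("s%d", 1:10)
  expect_equal(pca_fit(L)$explained_variance[1], 1, tolerance = 1e-12)
  expect_error(pca_fit(X, n_components = 5), "n_components")
})

test_that("Hotelling-T2 flags constructed outliers at the right rate", {
  set.seed(22)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(sprintf("s%02d", 1:40), sprintf("f%d", 1:5)))
  X[7, ] <- X[7, ] + 10
  m <- pca_fit(X, 2)
  fl <- flag_outliers(m)
  expect_true(fl[7])
  expect_false(any(flag_outliers(m, alpha = 1e-9)))  # cutoff -> Inf: no flags

  # null calibration: flag rate near alpha
  hits <- n_tot <- 0
  for (k in 1:100) {
    set.seed(3000 + k)
    Z <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(sprintf("s%03d", 1:200), sprintf("f%d", 1:4)))
    f <- flag_outliers(pca_fit(Z, 2), alpha = 0.05)
    hits <- hits + sum(f); n_tot <- n_tot + length(f)
  }
  expect_gt(hits / n_tot, 0.02)
  expect_lt(hits / n_tot, 0.08)
})

test_that("PCA-guided feature selection ranks structure above noise", {
  set.seed(23)
  t <- rnorm(40)
  X <- cbind(outer(t, c(3, 2.5, 2)), 0.05 * rnorm(40))
  colnames(X) <- c("a", "b", "c", "noise")
  rownames(X) <- sprintf("s%02d", 1:40)
  fm <- feature_matrix(X)
  m <- pca_fit(fm)
  expect_identical(feature_select(fm, m, keep_fraction = 1)$values, fm$values)
  rk <- attr(feature_select(fm, m, keep_fraction = 0.5), "ranking")
  expect_equal(rk$feature[nrow(rk)], "noise")
  expect_error(feature_select(fm, m, keep_fraction = 0), "keep_fraction")
})

test_that("LDA canonical directions match the closed-form Fisher direction", {
  set.seed(24)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3), n, 3) + cbind(rep(2, n), 0, 0),
             matrix(rnorm(n * 3), n, 3))
  colnames(X) <- c("x", "y", "z"); rownames(X) <- sprintf("s%03d", 1:(2 * n))
  lab <- rep(c("mut", "wt"), each = n)
  m <- lda_fit(X, lab)
  Sw <- cov(X[1:n, ]) * (n - 1) + cov(X[-(1:n), ]) * (n - 1)
  fisher <- solve(Sw, colMeans(X[1:n, ]) - colMeans(X[-(1:n), ]))
  cosine <- abs(sum(m$functions[, 1] * fisher)) /
    sqrt(sum(m$functions[, 1]^2) * sum(fisher^2))
  expect_gt(cosine, 0.99)
  expect_equal(ncol(m$functions), 1)   # two classes: one function

  # independent cross-check against MASS::lda scaling direction
  skip_if_not_installed("MASS")
  ml <- MASS::lda(X, lab)
  cosine2 <- abs(sum(m$functions[, 1] * ml$scaling[, 1])) /
    sqrt(sum(m$functions[, 1]^2) * sum(ml$scaling[, 1]^2))
  expect_gt(cosine2, 0.999)
})

test_that("LDA eigenstructure degenerates on collinear or shuffled classes", {
  set.seed(25)
  # three collinear class means: second eigenvalue ~ 0
  mu <- rbind(c(0, 0), c(1, 1), c(2, 2))
  X <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(40, sd = 0.3), 20, 2) + rep(mu[g, ], each = 20)))
  colnames(X) <- c("x", "y"); rownames(X) <- sprintf("s%02d", 1:60)
  lab <- rep(c("a", "b", "c"), each = 20)
  m <- lda_fit(X, lab)
  expect_lt(m$eigenvalues[2] / m$eigenvalues[1], 0.05)

  # permuted labels: no structure left
  set.seed(26)
  m0 <- lda_fit(X, sample(lab))
  expect_lt(m0$eigenvalues[1], 0.2 * m$eigenvalues[1])
  expect_error(lda_fit(X[1:3, ], c("a", "a", "b")), ">= 2 samples")
})

test_that("LDA prediction: training separability, ties, feature checks", {
  X <- rbind(matrix(c(0, 0, 0.1, 0.1, -0.1, 0.1), 3, 2, byrow = TRUE),
             matrix(c(5, 5, 5.1, 5.1, 4.9, 5.1), 3, 2, byrow = TRUE))
  colnames(X) <- c("x", "y"); rownames(X) <- sprintf("s%d", 1:6)
  lab <- rep(c("a", "b"), each = 3)
  m <- lda_fit(X, lab)
  expect_equal(lda_predict(m, X)$labels, lab)
  # exactly equidistant point: lexicographically smaller class wins
  m$centroids <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "CF1"))
  m$functions <- matrix(c(1, 0), 2, 1, dimnames = list(c("x", "y"), "CF1"))
  tie <- matrix(0, 1, 2, dimnames = list("t", c("x", "y")))
  expect_equal(lda_predict(m, tie)$labels, "a")
  wrong <- matrix(0, 1, 2, dimnames = list("t", c("p", "q")))
  expect_error(lda_predict(m, wrong), "feature")
})

test_that("NIPALS PLS agrees with the Krylov-subspace closed form", {
  set.seed(27)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(sprintf("s%d", 1:5),
                                               c("x", "y", "z")))
  y <- rnorm(5)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  for (A in 1:3) {
    b <- pls_coefficients(pls_fit(X, matrix(y), n_lv = A), A)
    expect_equal(unname(b[, 1]), unname(krylov_pls(Xc, yc, A)[, 1]),
                 tolerance = 1e-8)
  }
  # full-rank tall X with all LVs reproduces least squares
  b_ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(unname(pls_coefficients(pls_fit(X, matrix(y), 3), 3)[, 1]),
               b_ols, tolerance = 1e-8)
})

test_that("PLS internals: exact fit, orthogonal scores, shrinking residual", {
  set.seed(28)
  # orthogonal predictors: y proportional to one column is an exact 1-LV fit
  X <- qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE)))
  dimnames(X) <- list(sprintf("s%02d", 1:20), c("x", "y", "z"))
  y_lin <- X[, 2] * 2
  fit1 <- pls_fit(X, matrix(y_lin), n_lv = 1)
  pred <- pls_predict(fit1, X, 1)
  expect_equal(unname(pred[, 1]), unname(y_lin), tolerance = 1e-8)

  fit <- pls_fit(X, matrix(rnorm(20)), n_lv = 3)
  G <- crossprod(fit$scores)
  expect_true(all(abs(G[upper.tri(G)]) < 1e-6))
  expect_true(all(diff(fit$x_residual_ss) < 0))
  expect_error(pls_fit(X, matrix(rep(1, 20)), 2), "variance")
  expect_error(pls_fit(X, matrix(rnorm(20)), 25), "n_lv")
})

test_that("PLS-DA prediction: argmax labels, ties, batch consistency", {
  set.seed(29)
  X <- rbind(matrix(rnorm(40), 20, 2) + 4, matrix(rnorm(40), 20, 2))
  colnames(X) <- c("x", "y"); rownames(X) <- sprintf("s%02d", 1:40)
  lab <- rep(c("het", "wt"), each = 20)
  m <- plsda_fit(X, lab, n_lv = 2)
  pr <- plsda_predict(m, X)
  expect_gt(mean(pr$labels == lab), 0.95)
  expect_equal(colnames(pr$scores), c("het", "wt"))
  # single-sample prediction equals the batch row
  one <- plsda_predict(m, X[3, , drop = FALSE])
  expect_equal(one$scores[1, ], pr$scores[3, ])
  expect_equal(one$labels, pr$labels[3])
  # row permutation permutes scores identically
  idx <- sample(nrow(X))
  pr2 <- plsda_predict(m, X[idx, ])
  expect_equal(unname(pr2$scores), unname(pr$scores[idx, ]))
  # 0.5/0.5 dummy prediction: lexicographically smaller label
  stub <- m
  expect_equal(stub$classes[apply(matrix(c(0.5, 0.5), 1), 1, which.max)],
               "het")
})

test_that("marker recovery: injected channels dominate PLS-DA importance", {
  fm <- cohort_sift_matrix(n_per_group = 8, effects = marker_effects(3),
                           cohort_seed = 5, sift_seed = 6, block = "h3o")
  sc <- murivoc:::fold_scale(fm$values, fm$values)$train
  fit <- plsda_fit(sc, fm$metadata$genotype, n_lv = 3)
  top10 <- names(plsda_feature_importance(fit))[1:10]
  expect_true(all(marker_channels %in% top10))
})
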