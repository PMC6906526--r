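# Accept either a feature_matrix or a plain numeric matrix.
as_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a feature_matrix or numeric matrix")
}

#' Principal component decomposition for outlier screening
#'
#' Thin wrapper around [stats::prcomp()] (column-centred, unscaled) kept in
#' the shape the rest of the pipeline consumes: orthonormal loadings,
#' scores whose per-component variances equal the eigenvalues, and
#' explained-variance fractions.
#'
#' @param x a [feature_matrix()] or numeric matrix (samples x features).
#' @param n_components number of components (`<= min(n - 1, p)`).
#' @return A `pca_model`: `loadings`, `scores`, `eigenvalues`,
#'   `explained_variance` (fractions of total variance), `center`.
#' @export
pca_fit <- function(x, n_components = NULL) {
  v <- as_values(x)
  kmax <- min(nrow(v) - 1, ncol(v))
  if (is.null(n_components)) n_components <- kmax
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in [1, min(n - 1, p)]")
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  k <- n_components
  ev <- pc$sdev^2
  structure(list(loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 scores = pc$x[, seq_len(k), drop = FALSE],
                 eigenvalues = ev[seq_len(k)],
                 explained_variance = ev[seq_len(k)] / sum(ev),
                 center = pc$center,
                 n = nrow(v)),
            class = "pca_model")
}

#' Hotelling-T2 outlier flags from a PCA model
#'
#' Computes each sample's Hotelling T2 on the retained scores and flags
#' samples exceeding the F-distribution cutoff at level `alpha`. Flags are
#' advisory — nothing is removed.
#'
#' @param model a [pca_fit()] result with >= 2 components.
#' @param alpha flagging level (default 0.05).
#' @return Logical vector (one flag per sample), with the `t2` statistic
#'   and `cutoff` as attributes.
#' @export
flag_outliers <- function(model, alpha = 0.05) {
  k <- ncol(model$scores); n <- model$n
  if (k < 2) stop("flag_outliers needs a model with >= 2 components")
  if (n < k + 2) stop("too few samples for a T2 cutoff with this many components")
  t2 <- rowSums(sweep(model$scores^2, 2, model$eigenvalues, "/"))
  cutoff <- k * (n - 1) / (n - k) * qf(1 - alpha, k, n - k)
  flags <- t2 > cutoff
  attr(flags, "t2") <- t2
  attr(flags, "cutoff") <- cutoff
  flags
}

#' PCA-guided feature selection
#'
#' Ranks features by their maximum absolute loading across the leading
#' components that together explain at least `var_covered` of the variance,
#' and retains the top `keep_fraction`. Features orthogonal to the
#' dominant variance structure rank last.
#'
#' @param x a [feature_matrix()].
#' @param model a [pca_fit()] of the same matrix.
#' @param keep_fraction fraction of features to retain, in (0, 1].
#' @param var_covered cumulative explained-variance threshold choosing how
#'   many components vote (default 0.9).
#' @return The reduced [feature_matrix()]; the full ranking (data frame
#'   `feature`, `score`, `rank`) is attached as attribute `"ranking"`.
#' @export
feature_select <- function(x, model, keep_fraction = 0.5, var_covered = 0.9) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  v <- as_values(x)
  cum <- cumsum(model$explained_variance) / sum(model$explained_variance)
  m <- which(cum >= var_covered)[1]
  if (is.na(m)) m <- ncol(model$loadings)
  score <- apply(abs(model$loadings[, seq_len(m), drop = FALSE]), 1, max)
  ord <- order(score, decreasing = TRUE)
  n_keep <- max(1L, ceiling(keep_fraction * ncol(v)))
  keep <- sort(ord[seq_len(n_keep)])
  out <- if (inherits(x, "feature_matrix"))
    fm_replace(x, v[, keep, drop = FALSE]) else v[, keep, drop = FALSE]
  attr(out, "ranking") <- data.frame(
    feature = colnames(v)[ord], score = score[ord],
    rank = seq_along(ord), row.names = NULL, stringsAsFactors = FALSE)
  out
}

# Moore-Penrose pseudo-inverse via SVD with a relative tolerance.
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Linear discriminant analysis with canonical discriminant functions
#'
#' Canonical directions solve the generalized eigenproblem of
#' between-groups against within-groups scatter; when the within-groups
#' scatter is singular (more features than samples) it is inverted through
#' a pseudo-inverse (SVD, relative tolerance 1e-10). Directions are scaled
#' to unit pooled within-class variance. At most `n_classes - 1`
#' discriminant functions are returned, with non-increasing eigenvalues
#' (between/within variance ratios along each function).
#'
#' @param x a [feature_matrix()] or numeric matrix.
#' @param labels class labels (>= 2 classes, each with >= 2 samples).
#' @return An `lda_model`: `functions` (p x k coefficient matrix),
#'   `eigenvalues`, `centroids` (class means in canonical space),
#'   `classes`, `center`, `features`, `priors` (`"equal"`).
#' @export
lda_fit <- function(x, labels) {
  v <- as_values(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("lda_fit needs >= 2 classes")
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs >= 2 samples")
  n <- nrow(v); g <- length(classes)
  mu <- colMeans(v)
  vc <- sweep(v, 2, mu, "-")
  Sw <- matrix(0, ncol(v), ncol(v))
  Sb <- matrix(0, ncol(v), ncol(v))
  for (cl in classes) {
    xi <- vc[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    xi <- sweep(xi, 2, mi, "-")
    Sw <- Sw + crossprod(xi)
    Sb <- Sb + nrow(v[labels == cl, , drop = FALSE]) * tcrossprod(mi)
  }
  # symmetric reduction: Sw^{+1/2}' Sb Sw^{+1/2}
  es <- eigen(Sw, symmetric = TRUE)
  pos <- es$values > 1e-10 * max(es$values, 1e-300)
  W <- es$vectors[, pos, drop = FALSE] %*% diag(1 / sqrt(es$values[pos]),
                                                nrow = sum(pos))
  M <- t(W) %*% Sb %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- min(g - 1, sum(em$values > 1e-10 * max(em$values, 1e-300)))
  k <- max(k, 1L)
  A <- W %*% em$vectors[, seq_len(k), drop = FALSE]
  # unit pooled within-class variance along each canonical axis
  s2 <- diag(t(A) %*% Sw %*% A) / (n - g)
  s2[s2 <= 0] <- 1
  A <- sweep(A, 2, sqrt(s2), "/")
  colnames(A) <- paste0("CF", seq_len(k))
  cent <- vapply(classes, function(cl) {
    colMeans(v[labels == cl, , drop = FALSE] %*% A)
  }, numeric(k))
  centroids <- if (k == 1) matrix(cent, ncol = 1) else t(cent)
  dimnames(centroids) <- list(classes, colnames(A))
  structure(list(functions = A, eigenvalues = pmax(em$values[seq_len(k)], 0),
                 centroids = centroids, classes = classes, center = mu,
                 features = colnames(v), priors = "equal"),
            class = "lda_model")
}

#' Predict class membership from an LDA model
#'
#' Projects samples onto the canonical discriminant functions and assigns
#' the nearest class centroid (equal priors, Euclidean distance in
#' canonical space). Exact ties break to the lexicographically smaller
#' class label.
#'
#' @param model an [lda_fit()] result.
#' @param x samples with the same feature names as the training data.
#' @return List: `labels` (predicted classes), `scores` (canonical
#'   coordinates, for discriminant-function plots).
#' @export
lda_predict <- function(model, x) {
  v <- as_values(x)
  if (!is.null(model$features)) {
    if (is.null(colnames(v)) || !identical(colnames(v), model$features)) {
      if (is.null(colnames(v)) || !all(model$features %in% colnames(v)))
        stop("feature names do not match the fitted model")
      v <- v[, model$features, drop = FALSE]
    }
  }
  sc <- v %*% model$functions
  d2 <- vapply(seq_along(model$classes), function(i) {
    rowSums(sweep(sc, 2, model$centroids[i, ], "-")^2)
  }, numeric(nrow(sc)))
  d2 <- matrix(d2, nrow = nrow(sc))
  # classes are sorted, so the first minimum is the lexicographic tie-break
  lab <- model$classes[apply(d2, 1, which.min)]
  list(labels = lab, scores = sc)
}

#' NIPALS partial least squares regression
#'
#' Fits `n_lv` latent variables by the NIPALS sequence: per LV, a weight
#' vector from the X-Y covariance, X scores, X/Y loadings, then deflation
#' of both blocks. Score vectors are mutually orthogonal; for a univariate
#' response the first weight vector is proportional to X'y. Convergence
#' tolerance 1e-12 on the score vector, at most 500 iterations per LV.
#'
#' @param X predictor matrix (samples x features).
#' @param Y response matrix (samples x responses); internally centred
#'   together with X (centres stored).
#' @param n_lv number of latent variables (`<= min(n - 1, p)`).
#' @param tol,max_iter NIPALS convergence controls.
#' @return A `pls_model`: `weights` (W), `x_loadings` (P), `y_loadings`
#'   (C), `scores` (T), `x_center`, `y_center`, `n_lv`,
#'   `x_residual_ss`.
#' @export
pls_fit <- function(X, Y, n_lv, tol = 1e-12, max_iter = 500) {
  X <- as_values(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (n_lv < 1 || n_lv > min(nrow(X) - 1, ncol(X)))
    stop("n_lv must be in [1, min(n - 1, p)]")
  if (all(apply(Y, 2, var) == 0)) stop("Y has zero variance")
  xc <- colMeans(X); yc <- colMeans(Y)
  fit <- cpp_nipals(sweep(X, 2, xc, "-"), sweep(Y, 2, yc, "-"),
                    as.integer(n_lv), tol, as.integer(max_iter))
  if (fit$n_lv < 1) stop("NIPALS extracted no latent variable")
  rownames(fit$W) <- rownames(fit$P) <- colnames(X)
  rownames(fit$C) <- colnames(Y)
  structure(list(weights = fit$W, x_loadings = fit$P, y_loadings = fit$C,
                 scores = fit$T, x_center = xc, y_center = yc,
                 n_lv = fit$n_lv, x_residual_ss = fit$x_residual_ss,
                 features = colnames(X)),
            class = "pls_model")
}

#' Regression coefficients of a PLS model
#'
#' `B = W (P'W)^{-1} C'` using the first `a` latent variables.
#'
#' @param model a [pls_fit()] result.
#' @param a number of latent variables (default: all fitted).
#' @return p x q coefficient matrix (centred scale).
#' @export
pls_coefficients <- function(model, a = model$n_lv) {
  if (a < 1 || a > model$n_lv) stop("a out of range")
  W <- model$weights[, seq_len(a), drop = FALSE]
  P <- model$x_loadings[, seq_len(a), drop = FALSE]
  C <- model$y_loadings[, seq_len(a), drop = FALSE]
  W %*% solve(t(P) %*% W) %*% t(C)
}

#' @rdname pls_coefficients
#' @param X new samples.
#' @return For `pls_predict`: fitted response matrix on the original scale.
#' @export
pls_predict <- function(model, X, a = model$n_lv) {
  X <- as_values(X)
  B <- pls_coefficients(model, a)
  sweep(sweep(X, 2, model$x_center, "-") %*% B, 2, model$y_center, "+")
}

#' PLS discriminant analysis
#'
#' Wraps [pls_fit()] for classification: classes are dummy-coded one
#' column per class in `{0, 1}` (two-class problems keep both columns for
#' a symmetric argmax), optionally preceded by a PCA reduction retaining
#' the components covering `pca_var` of the variance
#' (`pca_prefilter = TRUE`).
#'
#' @param x training samples ([feature_matrix()] or matrix).
#' @param labels class labels.
#' @param n_lv number of latent variables.
#' @param pca_prefilter reduce X by PCA before the PLS fit.
#' @param pca_var variance fraction retained by the prefilter.
#' @inheritParams pls_fit
#' @return A `plsda_model` wrapping the `pls_model` plus the class map.
#' @export
plsda_fit <- function(x, labels, n_lv, pca_prefilter = FALSE, pca_var = 0.95,
                      tol = 1e-12, max_iter = 500) {
  v <- as_values(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("plsda_fit needs >= 2 classes")
  Y <- vapply(classes, function(cl) as.numeric(labels == cl),
              numeric(length(labels)))
  colnames(Y) <- classes
  pca <- NULL
  if (pca_prefilter) {
    pca <- pca_fit(v)
    m <- which(cumsum(pca$explained_variance) >= pca_var)[1]
    m <- max(m, 1L, na.rm = TRUE)
    pca$loadings <- pca$loadings[, seq_len(m), drop = FALSE]
    v <- sweep(v, 2, pca$center, "-") %*% pca$loadings
    colnames(v) <- paste0("PC", seq_len(m))
  }
  n_lv <- min(n_lv, nrow(v) - 1, ncol(v))
  pls <- pls_fit(v, Y, n_lv, tol, max_iter)
  structure(list(pls = pls, classes = classes, pca = pca,
                 features = colnames(as_values(x))),
            class = "plsda_model")
}

#' @rdname plsda_fit
#' @param model a `plsda_model`.
#' @param a number of latent variables used in prediction.
#' @return For `plsda_predict`: list `labels` (argmax class; ties break to
#'   the lexicographically smaller label), `scores` (predicted dummy
#'   block).
#' @export
plsda_predict <- function(model, x, a = model$pls$n_lv) {
  v <- as_values(x)
  if (!is.null(model$features) && !is.null(colnames(v)) &&
      !identical(colnames(v), model$features)) {
    if (!all(model$features %in% colnames(v)))
      stop("feature names do not match the fitted model")
    v <- v[, model$features, drop = FALSE]
  }
  if (!is.null(model$pca))
    v <- sweep(v, 2, model$pca$center, "-") %*% model$pca$loadings
  sc <- pls_predict(model$pls, v, a)
  # classes sorted; which.max takes the first maximum = lexicographic tie-break
  lab <- model$classes[apply(sc, 1, which.max)]
  list(labels = lab, scores = sc)
}

#' Feature importance of a PLS-DA model
#'
#' Per original feature, the summed absolute regression coefficients
#' across the class dummy block (mapped back through the PCA prefilter if
#' one was used). Used for marker recovery: injected effect channels
#' should rank near the top.
#'
#' @param model a `plsda_model`.
#' @param a number of latent variables (default: all).
#' @return Named numeric vector, decreasing order.
#' @export
plsda_feature_importance <- function(model, a = model$pls$n_lv) {
  B <- pls_coefficients(model$pls, a)
  if (!is.null(model$pca)) B <- model$pca$loadings %*% B
  imp <- rowSums(abs(B))
  names(imp) <- if (!is.null(model$pca)) rownames(model$pca$loadings)
                else rownames(B)
  sort(imp, decreasing = TRUE)
}

#' Serialize a fitted model to JSON
#'
#' Loadings, weights, centres and metadata of a `pca_model`, `lda_model`,
#' `pls_model` or `plsda_model`, written with full numeric precision.
#'
#' @param model a fitted model object.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  strip <- function(x) {
    if (is.matrix(x)) list(values = as.vector(x), dim = dim(x),
                           dimnames = dimnames(x))
    else x
  }
  payload <- lapply(unclass(model), function(el) {
    if (inherits(el, "pls_model") || inherits(el, "pca_model"))
      lapply(unclass(el), strip) else strip(el)
  })
  payload$class <- class(model)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}
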