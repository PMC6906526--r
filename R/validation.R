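#' Confusion counts and classification metrics
#'
#' `confusion_counts` tallies true/false positives/negatives against a
#' designated positive class (the mutant genotype, by convention).
#' `metrics_from_confusion` converts counts to percentages: accuracy
#' `(TP + TN) / total`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`. An empty denominator yields `NA` (undefined, not 0)
#' and sets the `undefined` attribute.
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive the positive class.
#' @return `confusion_counts`: a list of class `confusion_counts` with
#'   `tp`, `tn`, `fp`, `fn`, `positive`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  tpos <- truth == positive; ppos <- predicted == positive
  structure(list(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
                 fp = sum(!tpos & ppos), fn = sum(tpos & !ppos),
                 positive = positive),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param c a `confusion_counts` object.
#' @return `metrics_from_confusion`: named numeric vector
#'   `c(accuracy, specificity, sensitivity)` in percent.
#' @export
metrics_from_confusion <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("empty confusion table")
  acc <- 100 * (c$tp + c$tn) / total
  sens <- if (c$tp + c$fn > 0) 100 * c$tp / (c$tp + c$fn) else NA_real_
  spec <- if (c$tn + c$fp > 0) 100 * c$tn / (c$tn + c$fp) else NA_real_
  out <- c(accuracy = acc, specificity = spec, sensitivity = sens)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

# Apply a stored sqrt-standardization (train-fitted) to new samples.
apply_sqrt_standardize <- function(values, trained) {
  keep <- names(attr(trained, "center"))
  v <- sqrt(values[, keep, drop = FALSE])
  v <- sweep(v, 2, attr(trained, "center"), "-")
  sweep(v, 2, attr(trained, "scale"), "/")
}

#' Leave-one-out cross-validated LDA
#'
#' Each sample is predicted by an LDA model fitted on all other samples;
#' the square-root/standardization preprocessing is refit inside each fold
#' (no leakage: the held-out sample is transformed with the training
#' fold's centres and scales). The aggregate confusion across folds gives
#' accuracy/specificity/sensitivity.
#'
#' @param x a [feature_matrix()] or numeric non-negative matrix.
#' @param labels class labels (>= 3 samples per class).
#' @param positive positive class for sensitivity/specificity (default:
#'   the first non-`"wt"` class).
#' @param sqrt_transform refit [sqrt_standardize()] inside each fold
#'   (default TRUE).
#' @return A `validation_report` (protocol `"loo_cv_lda"`) with one
#'   iteration row per fold (the per-fold prediction) and aggregate
#'   metrics.
#' @export
loo_cv_lda <- function(x, labels, positive = NULL, sqrt_transform = TRUE) {
  v <- as_values(x)
  labels <- as.character(labels)
  if (any(table(labels) < 3)) stop("loo_cv_lda needs >= 3 samples per class")
  positive <- default_positive(labels, positive)
  n <- nrow(v)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- v[-i, , drop = FALSE]; te <- v[i, , drop = FALSE]
    if (sqrt_transform) {
      fmt <- sqrt_standardize(feature_matrix(
        tr, data.frame(sample_id = rownames(v)[-i])))
      te <- apply_sqrt_standardize(te, fmt)
      tr <- fmt$values
    }
    fit <- lda_fit(tr, labels[-i])
    pred[i] <- lda_predict(fit, te)$labels
  }
  cc <- confusion_counts(labels, pred, positive)
  m <- metrics_from_confusion(cc)
  structure(list(protocol = "loo_cv_lda",
                 iterations = data.frame(fold = seq_len(n), truth = labels,
                                         predicted = pred,
                                         stringsAsFactors = FALSE),
                 confusion = cc, aggregate = as.list(m),
                 positive = positive, n_folds = n),
            class = "validation_report")
}

default_positive <- function(labels, positive) {
  classes <- sort(unique(labels))
  if (!is.null(positive)) {
    if (!positive %in% classes) stop("positive class not present in labels")
    return(positive)
  }
  cand <- setdiff(classes, "wt")
  if (length(cand) > 0) cand[1] else classes[1]
}

#' Balanced train/test split
#'
#' Splits sample indices class by class: `round(train_frac * n_class)`
#' samples to the training side (clamped so both sides keep at least one
#' sample per class). Deterministic given the seed.
#'
#' @param labels class labels (every class >= 2 members).
#' @param train_frac training fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return List `train`, `test` of disjoint, exhaustive index vectors.
#' @export
balanced_split <- function(labels, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("every class needs >= 2 members to split")
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- min(max(round(train_frac * length(idx)), 1), length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# Lean LOO accuracy curve over 1..max_lv latent variables for PLS-DA on a
# (already scaled) training block; used for latent-variable selection.
# Returns mean LOO accuracy per number of LVs actually reachable in every
# fold.
plsda_loo_accuracy <- function(X, labels, max_lv, tol = 1e-12,
                               max_iter = 500) {
  n <- nrow(X)
  classes <- sort(unique(labels))
  Y <- vapply(classes, function(cl) as.numeric(labels == cl), numeric(n))
  max_lv <- min(max_lv, n - 2, ncol(X))
  correct <- cpp_plsda_loo(X, Y, match(labels, classes) - 1L,
                           as.integer(max_lv), tol, as.integer(max_iter))
  acc <- colMeans(correct == 1L)
  reachable <- colSums(correct >= 0L) == n
  acc[!reachable] <- -Inf    # only LV counts reachable in every fold compete
  acc
}

#' Select the number of PLS-DA latent variables by LOO-CV
#'
#' Fits leave-one-out cross-validation on the training block and returns
#' the number of latent variables maximizing mean LOO accuracy; ties break
#' toward the smaller number.
#'
#' @param X training matrix (samples x features), already scaled.
#' @param labels training labels.
#' @param max_lv largest candidate (default `min(n - 1, p, 10)`).
#' @return The chosen number of latent variables, with the accuracy curve
#'   as attribute `"loo_accuracy"`.
#' @export
select_n_lv_loocv <- function(X, labels, max_lv = NULL) {
  X <- as_values(X)
  if (is.null(max_lv)) max_lv <- min(nrow(X) - 1, ncol(X), 10)
  max_lv <- min(max_lv, nrow(X) - 2, ncol(X))
  if (max_lv <= 1) return(structure(1L, loo_accuracy = NA_real_))
  acc <- plsda_loo_accuracy(X, as.character(labels), max_lv)
  a <- which.max(acc)   # first maximum = smallest A on ties
  structure(as.integer(a), loo_accuracy = acc)
}

# In-fold autoscaling: centre/scale from the training block only.
fold_scale <- function(train, test) {
  mu <- colMeans(train)
  sdev <- apply(train, 2, sd)
  sdev[sdev <= 0] <- 1
  list(train = sweep(sweep(train, 2, mu, "-"), 2, sdev, "/"),
       test = sweep(sweep(test, 2, mu, "-"), 2, sdev, "/"))
}

#' Bootstrap-validated PLS-DA (balanced 70/30 subsampling)
#'
#' The resampling protocol: per iteration, a balanced random 70/30
#' train/test split; autoscaling fitted on the training block only; the
#' number of latent variables chosen by leave-one-out cross-validation on
#' the training block; a PLS-DA model fitted on the training block and
#' evaluated on the held-out test block; accuracy, specificity and
#' sensitivity recorded. Repeated `n_iter` times (iteration `i` uses seed
#' `seed + i`) and aggregated as the mean and standard deviation of the
#' per-iteration metrics. Despite the conventional name, the resampling is
#' subsampling without replacement, exactly as the 70/30 protocol states.
#'
#' @param x samples ([feature_matrix()] or matrix).
#' @param labels class labels (>= 4 samples per class).
#' @param n_iter number of split iterations (default 150).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer base seed.
#' @param max_lv largest candidate number of latent variables.
#' @param positive positive class (default: first non-`"wt"` class).
#' @param select_lv choose the number of LVs per iteration by LOO-CV
#'   (default TRUE; otherwise `max_lv` is used as-is).
#' @param scale_in_fold refit autoscaling inside each training fold
#'   (default TRUE, leakage-safe).
#' @param feature_select_fraction optional PCA-guided feature selection
#'   inside each training fold (see [feature_select()]): the fraction of
#'   features to retain, or `NULL` (default) for no selection. The PCA and
#'   the ranking are fitted on the training block only.
#' @return A `validation_report` (protocol `"bootstrap_plsda"`):
#'   `iterations` data frame (accuracy, specificity, sensitivity, chosen
#'   `n_lv` per iteration), `aggregate` means/sds, `seed`, `n_failed`.
#' @export
bootstrap_plsda <- function(x, labels, n_iter = 150, train_frac = 0.7,
                            seed = 1L, max_lv = 10, positive = NULL,
                            select_lv = TRUE, scale_in_fold = TRUE,
                            feature_select_fraction = NULL) {
  v <- as_values(x)
  labels <- as.character(labels)
  if (any(table(labels) < 4)) stop("bootstrap_plsda needs >= 4 samples per class")
  positive <- default_positive(labels, positive)
  rows <- vector("list", n_iter)
  failures <- character(0)
  for (i in seq_len(n_iter)) {
    rows[[i]] <- tryCatch({
      sp <- balanced_split(labels, train_frac, seed = seed + i)
      tr <- v[sp$train, , drop = FALSE]; te <- v[sp$test, , drop = FALSE]
      if (!is.null(feature_select_fraction)) {
        # selection on raw intensities (centred, unscaled PCA): spectral
        # variance concentrates on high-signal channels there
        pca <- pca_fit(tr)
        tr <- feature_select(tr, pca, feature_select_fraction)
        te <- te[, colnames(tr), drop = FALSE]
      }
      if (scale_in_fold) {
        sc <- fold_scale(tr, te); tr <- sc$train; te <- sc$test
      }
      a <- if (select_lv) select_n_lv_loocv(tr, labels[sp$train], max_lv)
           else min(max_lv, nrow(tr) - 1, ncol(tr))
      fit <- plsda_fit(tr, labels[sp$train], n_lv = a)
      pred <- plsda_predict(fit, te)
      m <- metrics_from_confusion(
        confusion_counts(labels[sp$test], pred$labels, positive))
      data.frame(iteration = i, accuracy = m[["accuracy"]],
                 specificity = m[["specificity"]],
                 sensitivity = m[["sensitivity"]],
                 n_lv = as.integer(a))
    }, error = function(e) {
      failures <<- c(failures, sprintf("iteration %d: %s", i, conditionMessage(e)))
      NULL
    })
  }
  it <- do.call(rbind, rows)
  if (is.null(it) || nrow(it) == 0) stop("all bootstrap iterations failed")
  agg <- list(
    mean_accuracy = mean(it$accuracy, na.rm = TRUE),
    sd_accuracy = sd(it$accuracy, na.rm = TRUE),
    mean_specificity = mean(it$specificity, na.rm = TRUE),
    sd_specificity = sd(it$specificity, na.rm = TRUE),
    mean_sensitivity = mean(it$sensitivity, na.rm = TRUE),
    sd_sensitivity = sd(it$sensitivity, na.rm = TRUE))
  structure(list(protocol = "bootstrap_plsda", iterations = it,
                 aggregate = agg, seed = seed, n_iter = n_iter,
                 train_frac = train_frac, positive = positive,
                 n_failed = length(failures), failures = failures),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s\n", x$protocol))
  if (!is.null(x$aggregate$mean_accuracy))
    cat(sprintf("  accuracy %.1f%%  specificity %.1f%%  sensitivity %.1f%%\n",
                x$aggregate$mean_accuracy, x$aggregate$mean_specificity,
                x$aggregate$mean_sensitivity))
  else
    cat(sprintf("  accuracy %.1f%%  specificity %.1f%%  sensitivity %.1f%%\n",
                x$aggregate$accuracy, x$aggregate$specificity,
                x$aggregate$sensitivity))
  invisible(x)
}

#' Permutation-null analysis of a classification protocol
#'
#' Re-runs the full resampling protocol on label permutations: per
#' permutation the class labels are shuffled once and the protocol is
#' executed end to end (with a reduced per-permutation iteration count,
#' default 20, since only the aggregate accuracy feeds the null). The
#' empirical p-value is `(1 + #{null >= observed}) / (n_perm + 1)`.
#' Density summaries of the observed per-iteration accuracies and of the
#' null accuracies support the usual two-density permutation plot.
#'
#' @inheritParams bootstrap_plsda
#' @param n_perm number of permutations (>= 20; default 150).
#' @param n_iter protocol iterations per permutation and for the observed
#'   run (default 20).
#' @param protocol the protocol function (default [bootstrap_plsda()]);
#'   must accept `(x, labels, n_iter, seed, ...)` and return a
#'   `validation_report`.
#' @param ... passed through to the protocol.
#' @return A `permutation_report`: `observed_accuracy`,
#'   `null_accuracies`, `p_value`, `observed_report`, `densities`
#'   (list of data frames `x`, `y`).
#' @export
permutation_null <- function(x, labels, n_perm = 150, seed = 1L, n_iter = 20,
                             protocol = bootstrap_plsda, ...) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  labels <- as.character(labels)
  observed <- protocol(x, labels, n_iter = n_iter,
                       seed = derive_seed(seed, 1L), ...)
  obs_acc <- observed$aggregate$mean_accuracy
  null_acc <- vapply(seq_len(n_perm), function(p) {
    perm <- with_seed(derive_seed(seed, 100L + p), sample(labels))
    rep <- protocol(x, perm, n_iter = n_iter,
                    seed = derive_seed(seed, 10000L + p), ...)
    rep$aggregate$mean_accuracy
  }, numeric(1))
  p_value <- (1 + sum(null_acc >= obs_acc)) / (n_perm + 1)
  dens <- function(v) {
    if (length(v) < 2 || sd(v) == 0)
      return(data.frame(x = mean(v), y = 1))
    d <- density(v)
    data.frame(x = d$x, y = d$y)
  }
  structure(list(observed_accuracy = obs_acc, null_accuracies = null_acc,
                 p_value = p_value, observed_report = observed,
                 densities = list(observed = dens(observed$iterations$accuracy),
                                  null = dens(null_acc)),
                 n_perm = n_perm, seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> observed %.1f%%, %d permutations, p = %.4g\n",
              x$observed_accuracy, x$n_perm, x$p_value))
  invisible(x)
}

#' Write a validation or permutation report as JSON
#'
#' @param report a `validation_report` or `permutation_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  payload <- unclass(report)
  payload$observed_report <- NULL
  payload$class <- class(report)
  jsonlite::write_json(payload, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
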