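#' Samples-by-features matrix with aligned sample metadata
#'
#' The common currency of the modelling layer: a numeric matrix whose rows
#' are samples (faecal headspace acquisitions) and whose columns are named
#' features (`"H3O+:61"`, `"GCMS:rt10.861"`, ...), carried together with a
#' metadata data frame (genotype, sex, age) aligned row-for-row.
#'
#' @param values numeric matrix; rownames are sample ids, colnames are
#'   feature names (unique, non-empty).
#' @param metadata data frame with a `sample_id` column matching
#'   `rownames(values)` in order; typically also `genotype`, `sex`,
#'   `age_weeks`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, metadata = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have sample ids as rownames")
  if (ncol(values) > 0 &&
      (is.null(colnames(values)) || anyDuplicated(colnames(values))))
    stop("`values` must have unique feature names as colnames")
  if (anyNA(values))
    stop("feature matrix must not contain missing values")
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(values),
                           stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(metadata))
    stop("metadata must contain a `sample_id` column")
  if (!identical(as.character(metadata$sample_id), rownames(values)))
    stop("metadata rows must align with the matrix rows (same ids, same order)")
  structure(list(values = values, metadata = metadata),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat("  features: ", paste(head(colnames(x$values), 5), collapse = ", "),
      if (ncol(x$values) > 5) ", ..." else "", "\n", sep = "")
  cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @rdname feature_matrix
#' @param x a `feature_matrix`.
#' @param ... unused.
#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

# Internal: subset samples, keeping metadata aligned.
fm_subset <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE],
                 fm$metadata[idx, , drop = FALSE])
}

# Internal: replace values, keep metadata.
fm_replace <- function(fm, values) feature_matrix(values, fm$metadata)

#' Write / read a feature matrix as CSV
#'
#' The values go to `<path>` with a leading `sample_id` column; metadata
#' goes to a sibling `<path stem>_metadata.csv`.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta_path <- sub("\\.csv$", "_metadata.csv", path)
  write.csv(fm$metadata, meta_path, row.names = FALSE)
  invisible(c(values = path, metadata = meta_path))
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  meta_path <- sub("\\.csv$", "_metadata.csv", path)
  metadata <- if (file.exists(meta_path))
    read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  feature_matrix(values, metadata)
}
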