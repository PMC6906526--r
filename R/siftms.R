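#' SIFT-MS spectrum container
#'
#' One sample's count-rate vector over integer m/z 10..140 for one
#' precursor ion.
#'
#' @param sample_id sample identifier.
#' @param precursor one of `"H3O+"`, `"NO+"`, `"O2+"`.
#' @param counts named non-negative numeric vector; names are integer m/z
#'   in 10..140.
#' @param sample_mass_g optional positive sample mass (grams).
#' @return An object of class `sift_spectrum`.
#' @export
sift_spectrum <- function(sample_id, precursor, counts, sample_mass_g = NULL) {
  precursor <- match.arg(precursor, c("H3O+", "NO+", "O2+"))
  mz <- as.integer(names(counts))
  if (anyNA(mz) || any(mz < 10 | mz > 140))
    stop("counts must be named by integer m/z in [10, 140]")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(sample_mass_g) && sample_mass_g <= 0)
    stop("sample_mass_g must be positive")
  structure(list(sample_id = sample_id, precursor = precursor,
                 counts = counts, sample_mass_g = sample_mass_g,
                 normalized = FALSE, qc_failed = FALSE),
            class = "sift_spectrum")
}

#' @export
print.sift_spectrum <- function(x, ...) {
  cat(sprintf("<sift_spectrum> %s [%s] %d channels%s%s\n", x$sample_id,
              x$precursor, length(x$counts),
              if (x$normalized) ", precursor-normalized" else "",
              if (x$qc_failed) ", QC FAILED" else ""))
  invisible(x)
}

#' Precursor reference channel
#'
#' @param precursor `"H3O+"`, `"NO+"` or `"O2+"`.
#' @return The reagent-ion m/z: 19, 30 or 32.
#' @export
precursor_mz <- function(precursor) {
  switch(precursor, "H3O+" = 19L, "NO+" = 30L, "O2+" = 32L,
         stop("unknown precursor"))
}

#' Normalize a spectrum to its precursor-ion count rate
#'
#' Every channel is divided by the reference precursor count of the same
#' acquisition, cancelling global intensity (flow, dilution, sample mass)
#' differences between samples. Under `reference = "own"` each spectrum
#' uses its own reagent-ion channel (m/z 19 for H3O+, 30 for NO+, 32 for
#' O2+); under `reference = "h3o19"` all three spectra of a sample are
#' divided by the H3O+ m/z 19 count (supply the matching H3O+ spectrum via
#' `h3o`). A zero or absent reference count marks the sample as a QC
#' failure (`qc_failed = TRUE`, counts untouched) rather than dropping it.
#'
#' @param spectrum a [sift_spectrum()].
#' @param reference `"own"` or `"h3o19"`.
#' @param h3o the sample's H3O+ spectrum (required for `"h3o19"` when
#'   `spectrum` is not itself H3O+).
#' @param mass_correct also divide by `sample_mass_g` when present.
#' @return The normalized `sift_spectrum` (reference channel equals 1).
#' @export
normalize_to_precursor <- function(spectrum, reference = c("own", "h3o19"),
                                   h3o = NULL, mass_correct = FALSE) {
  reference <- match.arg(reference)
  if (reference == "own" || spectrum$precursor == "H3O+") {
    ref_counts <- spectrum$counts
    ref_mz <- precursor_mz(if (reference == "own") spectrum$precursor
                           else "H3O+")
  } else {
    if (is.null(h3o) || h3o$precursor != "H3O+")
      stop("`h3o` spectrum required for reference = \"h3o19\"")
    ref_counts <- h3o$counts
    ref_mz <- 19L
  }
  ref <- ref_counts[as.character(ref_mz)]
  if (is.na(ref) || length(ref) == 0 || ref <= 0) {
    spectrum$qc_failed <- TRUE
    warning(sprintf("sample %s [%s]: zero/absent precursor count at m/z %d",
                    spectrum$sample_id, spectrum$precursor, ref_mz))
    return(spectrum)
  }
  spectrum$counts <- spectrum$counts / as.numeric(ref)
  if (mass_correct) {
    if (is.null(spectrum$sample_mass_g))
      stop("mass_correct = TRUE but sample_mass_g is absent")
    spectrum$counts <- spectrum$counts / spectrum$sample_mass_g
  }
  spectrum$normalized <- TRUE
  spectrum
}

# The 12 hydrate/isotopologue channels used for humidity diagnostics:
# reagent + hydrate cluster parents, their 17O-like (+1) and 18O-like (+2)
# satellites.
humidity_channels <- list(parent = c(19, 37, 55, 73),
                          iso1 = c(20, 38, 56, 74),
                          iso2 = c(21, 39, 57, 75))

#' Humidity diagnostics from H3O+ hydrate-cluster fractions
#'
#' For each H3O+ spectrum, computes the fraction of counts per second over
#' the 12 channels m/z 19/37/55/73 and their +1/+2 isotope satellites,
#' then averages the fractions per group (typically age). The report flags
#' any pair of groups whose average fraction on some channel differs by
#' more than one order of magnitude — the advisory check that sample
#' humidity stayed comparable across groups. Flags never filter samples.
#'
#' @param spectra list of H3O+ [sift_spectrum()] objects (raw counts).
#' @param group_key vector (length = samples) assigning each sample to a
#'   group, e.g. age in weeks.
#' @return A `humidity_report`: `per_sample` (fractions, rows sum to 1),
#'   `group_means`, `flagged_pairs` (data frame, possibly empty).
#' @export
humidity_fractions <- function(spectra, group_key) {
  if (any(vapply(spectra, function(s) s$precursor, "") != "H3O+"))
    stop("humidity diagnostics use H3O+ spectra only")
  if (length(group_key) != length(spectra))
    stop("group_key must have one entry per spectrum")
  channels <- unlist(humidity_channels, use.names = FALSE)
  frac <- t(vapply(spectra, function(s) {
    v <- s$counts[as.character(channels)]
    v[is.na(v)] <- 0
    tot <- sum(v)
    if (tot <= 0) stop(sprintf("sample %s: zero total over hydrate channels",
                               s$sample_id))
    v / tot
  }, numeric(length(channels))))
  colnames(frac) <- paste0("mz", channels)
  rownames(frac) <- vapply(spectra, function(s) s$sample_id, "")

  groups <- sort(unique(group_key))
  gm <- t(vapply(groups, function(g) {
    colMeans(frac[group_key == g, , drop = FALSE])
  }, numeric(ncol(frac))))
  rownames(gm) <- as.character(groups)

  flagged <- data.frame(group_a = character(), group_b = character(),
                        channel = character(), ratio = numeric(),
                        stringsAsFactors = FALSE)
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) for (j in seq(i + 1, length(groups))) {
      a <- gm[i, ]; b <- gm[j, ]
      pos <- a > 0 & b > 0
      r <- pmax(a[pos] / b[pos], b[pos] / a[pos])
      bad <- which(r > 10)
      if (length(bad) > 0)
        flagged <- rbind(flagged, data.frame(
          group_a = as.character(groups[i]), group_b = as.character(groups[j]),
          channel = names(r)[bad], ratio = unname(r[bad]),
          stringsAsFactors = FALSE))
    }
  }
  structure(list(per_sample = frac, group_means = gm,
                 flagged_pairs = flagged),
            class = "humidity_report")
}

#' @export
print.humidity_report <- function(x, ...) {
  cat(sprintf("<humidity_report> %d samples, %d groups, %d flagged pair(s)\n",
              nrow(x$per_sample), nrow(x$group_means), nrow(x$flagged_pairs)))
  invisible(x)
}

#' Assemble per-precursor spectra into a feature matrix
#'
#' @param spectra list of [sift_spectrum()] objects of one precursor.
#' @param metadata optional metadata data frame (`sample_id` aligned).
#' @return A [feature_matrix()] with features `"<precursor>:<mz>"`.
#' @export
sift_matrix <- function(spectra, metadata = NULL) {
  prec <- unique(vapply(spectra, function(s) s$precursor, ""))
  if (length(prec) != 1) stop("spectra must share one precursor")
  vals <- do.call(rbind, lapply(spectra, `[[`, "counts"))
  rownames(vals) <- vapply(spectra, function(s) s$sample_id, "")
  colnames(vals) <- paste0(prec, ":", names(spectra[[1]]$counts))
  feature_matrix(vals, metadata)
}

#' Reserved isotopologue/hydrate channels
#'
#' The 14 m/z values belonging to known isotopologue and hydrate reagent
#' ions, removed from every precursor block before multivariate analysis
#' (except on the LDA/canonical discriminant path, which retains them).
#' @export
reserved_mz <- c(19, 21, 30, 32, 34, 37, 39, 48, 55, 57, 66, 73, 75, 91)

#' Remove reserved isotopologue/hydrate channels
#'
#' Drops the 14 [reserved_mz] channels from every precursor block of the
#' matrix. Removing channels that are already absent is a no-op;
#' `keep_for_lda = TRUE` returns the matrix unchanged (the LDA path keeps
#' all channels). Idempotent.
#'
#' @param fm a [feature_matrix()] with `"<precursor>:<mz>"` feature names.
#' @param keep_for_lda keep everything (LDA/canonical-discriminant path).
#' @return The reduced `feature_matrix`.
#' @export
drop_reserved_channels <- function(fm, keep_for_lda = FALSE) {
  if (keep_for_lda) return(fm)
  mz <- sub("^.*:(rt)?", "", colnames(fm$values))
  drop <- suppressWarnings(as.numeric(mz)) %in% reserved_mz &
    grepl("^(H3O|NO|O2)\\+:", colnames(fm$values))
  fm_replace(fm, fm$values[, !drop, drop = FALSE])
}

#' Concatenate the three precursor blocks into one dataset
#'
#' Column-wise concatenation of the H3O+, NO+ and O2+ feature blocks for
#' identical sample sets in identical order; feature names stay
#' precursor-prefixed. An empty block (0 features) is skipped with a
#' warning.
#'
#' @param h3o,no,o2 [feature_matrix()] objects over the same samples.
#' @return The combined `feature_matrix`.
#' @export
combine_precursors <- function(h3o, no, o2) {
  blocks <- list(h3o, no, o2)
  ids <- lapply(blocks, function(b) rownames(b$values))
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]])))
    stop("sample sets/order differ between precursor blocks")
  empty <- vapply(blocks, function(b) ncol(b$values) == 0, TRUE)
  if (any(empty)) {
    warning("empty precursor block(s) skipped in combination")
    blocks <- blocks[!empty]
  }
  vals <- do.call(cbind, lapply(blocks, `[[`, "values"))
  feature_matrix(vals, blocks[[1]]$metadata)
}

#' Square-root transform and standardize
#'
#' Applies the square-root transformation (variance stabilization for
#' skewed, non-negative spectral intensities), then centres each column to
#' mean 0 and scales to standard deviation 1 (sample sd, n-1 denominator).
#' Constant columns (sd = 0 after transformation) cannot be standardized
#' and are dropped; their names are recorded in the `dropped` attribute.
#'
#' @param fm a [feature_matrix()] with non-negative values.
#' @return The standardized `feature_matrix`.
#' @export
sqrt_standardize <- function(fm) {
  if (any(fm$values < 0)) stop("sqrt_standardize requires non-negative values")
  v <- sqrt(fm$values)
  mu <- colMeans(v)
  sdev <- apply(v, 2, sd)
  keep <- sdev > 0
  v <- sweep(v[, keep, drop = FALSE], 2, mu[keep], "-")
  v <- sweep(v, 2, sdev[keep], "/")
  out <- fm_replace(fm, v)
  attr(out, "dropped") <- colnames(fm$values)[!keep]
  attr(out, "center") <- mu[keep]
  attr(out, "scale") <- sdev[keep]
  out
}

#' Feature scaling: auto-scaling, range-scaling, row normalisation
#'
#' `AS` (auto-scaling): per column, subtract the mean and divide by the
#' sample standard deviation. `RS` (range-scaling): per column, subtract
#' the mean and divide by the range (max - min). `NRM` (normalisation):
#' divide each row by its Euclidean norm. Degenerate columns (zero sd for
#' AS, zero range for RS) are dropped with a warning; a zero-norm row
#' under NRM is an error.
#'
#' @param fm a [feature_matrix()].
#' @param method `"AS"`, `"RS"` or `"NRM"`.
#' @return The scaled `feature_matrix`.
#' @export
scale_features <- function(fm, method = c("AS", "RS", "NRM")) {
  method <- match.arg(method)
  v <- fm$values
  if (method == "NRM") {
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) stop("zero-norm row under NRM scaling")
    return(fm_replace(fm, v / nrm))
  }
  mu <- colMeans(v)
  den <- if (method == "AS") apply(v, 2, sd)
         else apply(v, 2, max) - apply(v, 2, min)
  keep <- den > 0
  if (!all(keep))
    warning(sprintf("%d degenerate column(s) dropped under %s scaling",
                    sum(!keep), method))
  v <- sweep(v[, keep, drop = FALSE], 2, mu[keep], "-")
  v <- sweep(v, 2, den[keep], "/")
  fm_replace(fm, v)
}

#' Write a humidity report as JSON
#'
#' @param report a `humidity_report`.
#' @param path output path.
#' @export
write_humidity_report <- function(report, path) {
  jsonlite::write_json(
    list(per_sample = as.data.frame(report$per_sample),
         group_means = as.data.frame(report$group_means),
         flagged_pairs = report$flagged_pairs),
    path, dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(path)
}
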