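#' GC-MS peak table
#'
#' One run's list of (retention time, area, label) peaks, with exactly one
#' peak designated as the internal standard (d8-toluene in the generator).
#'
#' @param sample_id run identifier.
#' @param peaks data frame with columns `rt_min` (>= 0), `area` (>= 0) and
#'   optionally `label`.
#' @param internal_standard_label label marking the internal-standard peak,
#'   or `NULL` with `internal_standard_rt` given instead.
#' @param internal_standard_rt retention time of the internal standard; the
#'   nearest peak is designated.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(sample_id, peaks, internal_standard_label = NULL,
                       internal_standard_rt = NULL) {
  if (!all(c("rt_min", "area") %in% names(peaks)))
    stop("peaks must have rt_min and area columns")
  if (any(peaks$rt_min < 0)) stop("retention times must be >= 0")
  if (any(peaks$area < 0)) stop("areas must be non-negative")
  if (is.null(peaks$label))
    peaks$label <- rep(NA_character_, nrow(peaks))
  if (nrow(peaks) == 0)   # empty run: no IS to designate, flagged downstream
    return(structure(list(sample_id = sample_id, peaks = peaks,
                          internal_standard_rt = NA_real_,
                          is_index = NA_integer_, normalized = FALSE,
                          qc_failed = FALSE),
                     class = "peak_table"))
  is_idx <- integer(0)
  if (!is.null(internal_standard_label))
    is_idx <- which(peaks$label == internal_standard_label)
  else if (!is.null(internal_standard_rt))
    is_idx <- which.min(abs(peaks$rt_min - internal_standard_rt))
  if (length(is_idx) != 1)
    stop("exactly one internal-standard peak must be designated")
  structure(list(sample_id = sample_id, peaks = peaks,
                 internal_standard_rt = peaks$rt_min[is_idx],
                 is_index = is_idx, normalized = FALSE, qc_failed = FALSE),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %s: %d peaks, IS at %.3f min%s%s\n", x$sample_id,
              nrow(x$peaks), x$internal_standard_rt,
              if (x$normalized) ", IS-normalized" else "",
              if (x$qc_failed) ", QC FAILED" else ""))
  invisible(x)
}

#' Normalize peak areas to the internal standard
#'
#' Divides every area by the internal-standard peak area of the same run,
#' cancelling run-level intensity factors; the normalized IS area is 1. A
#' missing or zero-area internal standard marks the run as a QC failure
#' (areas untouched) instead of dropping it.
#'
#' @param table a [peak_table()].
#' @return The normalized `peak_table`.
#' @export
normalize_internal_standard <- function(table) {
  if (nrow(table$peaks) == 0) {   # empty run still participates, all-zero row
    table$normalized <- TRUE
    return(table)
  }
  is_area <- table$peaks$area[table$is_index]
  if (length(is_area) != 1 || is.na(is_area) || is_area <= 0) {
    table$qc_failed <- TRUE
    warning(sprintf("run %s: missing/zero internal-standard area",
                    table$sample_id))
    return(table)
  }
  table$peaks$area <- table$peaks$area / is_area
  table$normalized <- TRUE
  table
}

# Reference segment boundaries (0-based indices) for COW: the reference is
# cut into ~equal segments of the requested nominal length.
cow_bounds <- function(n_ref, segment_len) {
  n_seg <- max(1L, as.integer(round((n_ref - 1) / segment_len)))
  as.integer(round(seq(0, n_ref - 1, length.out = n_seg + 1)))
}

#' Correlation optimised warping of one trace onto a reference
#'
#' Cuts the reference into segments of nominal length `segment_len` points
#' and searches, by dynamic programming, the placement of the matching
#' sample-segment boundaries — each sample segment allowed to stretch or
#' shrink by up to `slack` points — that maximizes the summed Pearson
#' correlation between reference segments and linearly interpolated sample
#' segments. All-constant segments contribute correlation 0 (flat baseline
#' neither rewards nor punishes warping). Among equal-score paths the one
#' with minimal cumulative absolute stretch is returned, so the
#' minimal-deformation alignment is reproducible.
#'
#' @param reference,sample numeric intensity vectors (the RT grids are
#'   implicit; both traces must have length >= `2 * segment_len`).
#' @param segment_len nominal segment length in points (default 30).
#' @param slack allowed boundary displacement in points
#'   (`1 <= slack < segment_len`, default 3).
#' @return A list: `warped` (sample resampled to the reference length),
#'   `path` (a `warp_path`: node pairs of 1-based reference/sample
#'   boundary indices, per-segment correlations, total score).
#' @export
cow_align <- function(reference, sample, segment_len = 30, slack = 3) {
  reference <- as.numeric(reference); sample <- as.numeric(sample)
  if (length(reference) < 2 * segment_len || length(sample) < 2 * segment_len)
    stop("both traces must have length >= 2 * segment_len")
  if (slack < 1 || slack >= segment_len)
    stop("slack must satisfy 1 <= slack < segment_len")
  bounds <- cow_bounds(length(reference), segment_len)
  res <- cpp_cow(reference, sample, bounds, as.integer(slack))
  path <- structure(list(
    nodes = cbind(reference = bounds + 1L,
                  sample = as.integer(res$sample_bounds) + 1L),
    segment_scores = as.numeric(res$segment_scores),
    total_score = res$total_score,
    total_stretch = res$total_stretch), class = "warp_path")
  list(warped = as.numeric(res$warped), path = path)
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> %d segments, total score %.4f, stretch %g\n",
              length(x$segment_scores), x$total_score, x$total_stretch))
  invisible(x)
}

#' Align a set of traces to a common reference
#'
#' Warps every trace onto the reference trace (by default the first one)
#' with [cow_align()]. Peak-only data cannot be warped: call this on dense
#' traces, then re-extract peaks.
#'
#' @param traces list of numeric vectors or data frames with an
#'   `intensity` column.
#' @param reference_index which trace to use as reference.
#' @inheritParams cow_align
#' @return List of `warped` (list of aligned vectors, reference included
#'   unchanged) and `paths`.
#' @export
cow_align_set <- function(traces, reference_index = 1, segment_len = 30,
                          slack = 3) {
  get_int <- function(tr) if (is.data.frame(tr)) tr$intensity else tr
  ref <- get_int(traces[[reference_index]])
  out <- vector("list", length(traces)); paths <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    if (i == reference_index) { out[[i]] <- ref; next }
    a <- cow_align(ref, get_int(traces[[i]]), segment_len, slack)
    out[[i]] <- a$warped; paths[[i]] <- a$path
  }
  list(warped = out, paths = paths)
}

#' Simple local-maximum peak extraction from a dense trace
#'
#' Supports the synthetic round-trip (simulate -> warp -> re-extract).
#' A point is a peak if it is a strict local maximum above
#' `min_height`; the area is approximated by trapezoidal integration over
#' the surrounding region above 1% of the apex.
#'
#' @param trace data frame with `rt_min` and `intensity`.
#' @param min_height minimal apex intensity.
#' @return Data frame `rt_min`, `area`.
#' @export
find_peaks <- function(trace, min_height) {
  y <- trace$intensity; x <- trace$rt_min
  n <- length(y)
  apex <- which(y > min_height & y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  out <- lapply(apex, function(i) {
    thr <- 0.01 * y[i]
    l <- i; while (l > 1 && y[l - 1] > thr && y[l - 1] <= y[l]) l <- l - 1
    r <- i; while (r < n && y[r + 1] > thr && y[r + 1] <= y[r]) r <- r + 1
    idx <- l:r
    area <- sum(diff(x[idx]) * (head(y[idx], -1) + y[idx][-1]) / 2)
    data.frame(rt_min = x[i], area = area)
  })
  if (length(out) == 0) return(data.frame(rt_min = numeric(), area = numeric()))
  do.call(rbind, out)
}

#' Build a feature matrix from IS-normalized peak tables
#'
#' Peaks from all runs are greedily clustered on retention time
#' (single linkage: consecutive peaks closer than `rt_tolerance_min` join
#' one cluster). Each cluster becomes a feature `"GCMS:rt<center>"`
#' (centre = mean RT, 3 decimals); a sample missing a cluster's peak is
#' imputed 0; multiple peaks of one sample in a cluster are summed; the
#' cluster label is the majority peak label, if any.
#'
#' @param tables list of IS-normalized [peak_table()] objects.
#' @param rt_tolerance_min single-linkage RT tolerance in minutes
#'   (default 0.1).
#' @param metadata optional metadata (aligned with `tables`).
#' @param drop_internal_standard remove the internal-standard peaks before
#'   clustering (default TRUE; their normalized area is identically 1).
#' @return A [feature_matrix()]; cluster labels in the
#'   `"feature_labels"` attribute.
#' @export
build_gcms_matrix <- function(tables, rt_tolerance_min = 0.1, metadata = NULL,
                              drop_internal_standard = TRUE) {
  if (any(!vapply(tables, function(t) t$normalized || t$qc_failed, TRUE)))
    stop("peak tables must be IS-normalized first (see normalize_internal_standard)")
  ids <- vapply(tables, `[[`, "", "sample_id")
  all_peaks <- do.call(rbind, lapply(seq_along(tables), function(i) {
    pk <- tables[[i]]$peaks
    if (drop_internal_standard && nrow(pk) > 0)
      pk <- pk[-tables[[i]]$is_index, , drop = FALSE]
    if (nrow(pk) == 0) return(NULL)
    data.frame(sample = i, pk, stringsAsFactors = FALSE)
  }))

  if (is.null(all_peaks) || nrow(all_peaks) == 0) {
    vals <- matrix(0, nrow = length(tables), ncol = 0,
                   dimnames = list(ids, NULL))
    return(feature_matrix(vals, metadata))
  }
  ord <- order(all_peaks$rt_min)
  all_peaks <- all_peaks[ord, ]
  gap <- c(FALSE, diff(all_peaks$rt_min) > rt_tolerance_min)
  cluster <- cumsum(gap) + 1L

  centers <- tapply(all_peaks$rt_min, cluster, mean)
  fnames <- sprintf("GCMS:rt%.3f", centers)
  labels <- vapply(split(all_peaks$label, cluster), function(l) {
    l <- l[!is.na(l)]
    if (length(l) == 0) return(NA_character_)
    names(sort(table(l), decreasing = TRUE))[1]
  }, "")

  vals <- matrix(0, nrow = length(tables), ncol = length(centers),
                 dimnames = list(ids, fnames))
  for (k in seq_len(nrow(all_peaks)))
    vals[all_peaks$sample[k], cluster[k]] <-
      vals[all_peaks$sample[k], cluster[k]] + all_peaks$area[k]

  out <- feature_matrix(vals, metadata)
  attr(out, "feature_labels") <- setNames(unname(labels), fnames)
  out
}

#' Read GC-MS peak tables from a long CSV
#'
#' Expects columns `sample_id`, `rt_min`, `area`, `label`; the internal
#' standard is identified by `internal_standard_label`.
#'
#' @param path CSV path.
#' @param internal_standard_label label of the IS peak in each run.
#' @return List of [peak_table()] objects.
#' @export
read_gcms_peaks <- function(path, internal_standard_label = "d8-toluene (IS)") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$sample_id), function(d) {
    peak_table(d$sample_id[1], d[, c("rt_min", "area", "label")],
               internal_standard_label = internal_standard_label)
  })
}
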