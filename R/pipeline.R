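#' Pipeline configuration
#'
#' One object holding every choice of the end-to-end study analogue:
#' cohort design, preprocessing options, validation options and the
#' comparison specification. The master `seed` drives every stage.
#'
#' @param cohort a [cohort_config()].
#' @param seed master integer seed (mandatory; stage seeds are derived).
#' @param reference precursor normalization scheme, `"own"` or `"h3o19"`.
#' @param drop_reserved remove the reserved isotopologue/hydrate channels
#'   (the LDA path keeps them regardless).
#' @param scaling extra feature scaling before validation: `"none"`,
#'   `"AS"`, `"RS"` or `"NRM"` (the bootstrap protocol additionally
#'   autoscales inside each training fold).
#' @param label_col metadata column defining the classes.
#' @param positive positive class label.
#' @param stratify_by_age analyze each age separately plus a pooled
#'   `"all"` stratum (default TRUE).
#' @param n_iter,n_perm,train_frac,max_lv validation options (see
#'   [bootstrap_plsda()] and [permutation_null()]).
#' @param gcms_enabled also run the GC-MS path (simulate, IS-normalize,
#'   COW-align traces, RT feature matrix, validation).
#' @param segment_len,slack,rt_tolerance_min GC-MS alignment/assembly
#'   options.
#' @param sift_effects,gcms_effects effect panels for the generators.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = 1L,
                            reference = c("own", "h3o19"),
                            drop_reserved = TRUE,
                            scaling = c("none", "AS", "RS", "NRM"),
                            label_col = "genotype", positive = "het",
                            stratify_by_age = TRUE,
                            n_iter = 50, n_perm = 20, train_frac = 0.7,
                            max_lv = 10,
                            gcms_enabled = FALSE, segment_len = 30, slack = 3,
                            rt_tolerance_min = 0.1,
                            sift_effects = default_sift_effects(),
                            gcms_effects = default_gcms_effects()) {
  structure(list(cohort = cohort, seed = as.integer(seed),
                 reference = match.arg(reference),
                 drop_reserved = drop_reserved,
                 scaling = match.arg(scaling), label_col = label_col,
                 positive = positive, stratify_by_age = stratify_by_age,
                 n_iter = n_iter, n_perm = n_perm, train_frac = train_frac,
                 max_lv = max_lv, gcms_enabled = gcms_enabled,
                 segment_len = segment_len, slack = slack,
                 rt_tolerance_min = rt_tolerance_min,
                 sift_effects = sift_effects, gcms_effects = gcms_effects),
            class = "pipeline_config")
}

#' Normalize per-precursor count matrices to the precursor channel
#'
#' Matrix-level counterpart of [normalize_to_precursor()]: each row
#' (sample) of each block is divided by its reference precursor count
#' (own reagent channel, or the H3O+ m/z 19 count under `"h3o19"`).
#' Samples with non-positive reference counts are reported in the
#' `qc_failed` attribute and left unnormalized.
#'
#' @param mats named list of the three raw [feature_matrix()] blocks
#'   (`"H3O+"`, `"NO+"`, `"O2+"`), as from [simulate_sift_cohort()].
#' @param reference `"own"` or `"h3o19"`.
#' @return The list with normalized blocks.
#' @export
normalize_sift_matrices <- function(mats, reference = c("own", "h3o19")) {
  reference <- match.arg(reference)
  h3o_ref <- mats[["H3O+"]]$values[, "H3O+:19"]
  lapply_named <- function(prec) {
    fm <- mats[[prec]]
    ref <- if (reference == "own")
      fm$values[, paste0(prec, ":", precursor_mz(prec))] else h3o_ref
    bad <- !(ref > 0)
    vals <- fm$values
    vals[!bad, ] <- vals[!bad, , drop = FALSE] / ref[!bad]
    out <- fm_replace(fm, vals)
    attr(out, "qc_failed") <- rownames(vals)[bad]
    out
  }
  out <- lapply(c("H3O+", "NO+", "O2+"), lapply_named)
  names(out) <- c("H3O+", "NO+", "O2+")
  out
}

run_validation <- function(values, labels, cfg, seed) {
  vr <- bootstrap_plsda(values, labels, n_iter = cfg$n_iter,
                        train_frac = cfg$train_frac, seed = seed,
                        max_lv = cfg$max_lv, positive = cfg$positive)
  pr <- permutation_null(values, labels, n_perm = cfg$n_perm,
                         seed = derive_seed(seed, 3L),
                         n_iter = min(cfg$n_iter, 20),
                         train_frac = cfg$train_frac, max_lv = cfg$max_lv,
                         positive = cfg$positive)
  list(validation = vr, permutation = pr)
}

stratum_ids <- function(meta, cfg) {
  strata <- list(all = rep(TRUE, nrow(meta)))
  if (cfg$stratify_by_age)
    for (a in sort(unique(meta$age_weeks)))
      strata[[sprintf("age%02d", a)]] <- meta$age_weeks == a
  strata
}

#' Run the end-to-end study analogue
#'
#' simulate -> preprocess -> validate -> report, from one configuration:
#' generates the cohort and its SIFT-MS (and optionally GC-MS)
#' acquisitions, normalizes to the precursor ion, removes reserved
#' channels, concatenates the precursor blocks, and for each age stratum
#' (plus the pooled stratum) runs the bootstrap PLS-DA protocol and its
#' permutation null. Every report, score CSV and the manifest are written
#' under `out_dir`; the manifest records the configuration, every derived
#' seed and an MD5 checksum of every output file, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return The manifest (invisibly written as `manifest.json`), with all
#'   reports attached in the `results` element.
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  cohort <- generate_cohort(cfg$cohort)
  log_stage("simulate", "cohort: %d animals x %d ages",
            nrow(cohort$animals), length(cfg$cohort$ages_weeks))
  write_cohort(cohort, out_dir)

  sift <- simulate_sift_cohort(cohort, cfg$sift_effects,
                               seed = derive_seed(cfg$seed, 11L))
  norm <- normalize_sift_matrices(sift[c("H3O+", "NO+", "O2+")],
                                  cfg$reference)
  blocks <- lapply(norm, function(b)
    drop_reserved_channels(b, keep_for_lda = !cfg$drop_reserved))
  combined <- combine_precursors(blocks[["H3O+"]], blocks[["NO+"]],
                                 blocks[["O2+"]])
  if (cfg$scaling != "none") combined <- scale_features(combined, cfg$scaling)
  log_stage("preprocess", "combined SIFT matrix: %d x %d",
            nrow(combined$values), ncol(combined$values))
  write_feature_matrix(combined, file.path(out_dir, "sift_features.csv"))

  matrices <- list(sift = combined)
  if (cfg$gcms_enabled) {
    gc <- simulate_gcms_cohort(cohort, cfg$gcms_effects,
                               seed = derive_seed(cfg$seed, 12L))
    aligned <- cow_align_set(gc$traces, segment_len = cfg$segment_len,
                             slack = cfg$slack)
    tables <- lapply(gc$tables, normalize_internal_standard)
    gmat <- build_gcms_matrix(tables, cfg$rt_tolerance_min,
                              metadata = gc$metadata)
    log_stage("preprocess", "GC-MS matrix: %d x %d (COW total scores %.1f..%.1f)",
              nrow(gmat$values), ncol(gmat$values),
              min(vapply(aligned$paths[-1], function(p) p$total_score, 1)),
              max(vapply(aligned$paths[-1], function(p) p$total_score, 1)))
    write_feature_matrix(gmat, file.path(out_dir, "gcms_features.csv"))
    jsonlite::write_json(
      lapply(aligned$paths[-1], function(p)
        list(nodes = p$nodes, total_score = p$total_score)),
      file.path(out_dir, "warp_paths.json"), digits = NA)
    matrices$gcms <- gmat
  }

  results <- list()
  for (modality in names(matrices)) {
    fm <- matrices[[modality]]
    meta <- fm$metadata
    labels <- meta[[cfg$label_col]]
    strata <- stratum_ids(meta, cfg)
    for (sn in names(strata)) {
      keep <- strata[[sn]]
      lab <- labels[keep]
      if (length(unique(lab)) < 2 || any(table(lab) < 4)) next
      vals <- fm$values[keep, , drop = FALSE]
      seed_s <- derive_seed(cfg$seed, 1000L + length(results))
      res <- run_validation(vals, lab, cfg, seed_s)
      log_stage("validate", "%s/%s: accuracy %.1f%%, p = %.4g", modality, sn,
                res$validation$aggregate$mean_accuracy,
                res$permutation$p_value)
      tag <- sprintf("%s_%s", modality, sn)
      write_report_json(res$validation,
                        file.path(out_dir, sprintf("validation_%s.json", tag)))
      write_report_json(res$permutation,
                        file.path(out_dir, sprintf("permutation_%s.json", tag)))
      # score plot export: PLS-DA fitted once on the stratum for LV1/LV2
      fit <- plsda_fit(fold_scale(vals, vals)$train, lab,
                       n_lv = min(2, nrow(vals) - 1))
      sc <- fit$pls$scores
      utils::write.csv(
        data.frame(sample_id = rownames(vals), LV1 = sc[, 1],
                   LV2 = if (ncol(sc) > 1) sc[, 2] else NA_real_,
                   label = lab),
        file.path(out_dir, sprintf("scores_%s.csv", tag)), row.names = FALSE)
      results[[tag]] <- list(seed = seed_s,
                             accuracy = res$validation$aggregate$mean_accuracy,
                             p_value = res$permutation$p_value,
                             validation = res$validation,
                             permutation = res$permutation)
    }
  }

  cfg_json <- file.path(out_dir, "config.json")
  cfg_out <- unclass(cfg)
  cfg_out$cohort <- unclass(cfg$cohort)
  cfg_out$sift_effects <- within(cfg$sift_effects,
                                 age_trend <- lapply(age_trend, as.list))
  cfg_out$gcms_effects <- within(cfg$gcms_effects,
                                 age_trend <- lapply(age_trend, as.list))
  jsonlite::write_json(cfg_out, cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "columns")

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    package = "murivoc",
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    comparisons = lapply(results, function(r)
      list(seed = r$seed, accuracy = r$accuracy, p_value = r$p_value)),
    files = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}
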