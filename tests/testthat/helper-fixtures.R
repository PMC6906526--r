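# Shared fixture builders (all generated in code, deterministic by seed).

noise_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("s%03d", seq_len(n)),
                         sprintf("f%03d", seq_len(p))))
}

# A full H3O+ style spectrum covering m/z 10..140.
full_h3o <- function(sample_id = "a", value = 100) {
  counts <- rep(value, 131)
  names(counts) <- 10:140
  sift_spectrum(sample_id, "H3O+", counts)
}

# The Table-2 marker channels used in the power construction.
marker_channels <- c("H3O+:61", "H3O+:79", "H3O+:89", "H3O+:47", "H3O+:59")

marker_effects <- function(magnitude = 3) {
  rbind(sift_effect("H3O+", 61, magnitude), sift_effect("H3O+", 79, magnitude),
        sift_effect("H3O+", 89, magnitude), sift_effect("H3O+", 47, magnitude),
        sift_effect("H3O+", 59, magnitude))
}

# One-age het/wt cohort run through the SIFT-MS path; returns the combined
# (or H3O+-only) precursor-normalized matrix with reserved channels removed.
cohort_sift_matrix <- function(n_per_group = 10, effect_scale = 1,
                               effects = default_sift_effects(),
                               cohort_seed = 1, sift_seed = 2,
                               age = 12, block = c("combined", "h3o")) {
  block <- match.arg(block)
  co <- generate_cohort(cohort_config(n_per_group = n_per_group,
                                      ages_weeks = age, seed = cohort_seed,
                                      effect_scale = effect_scale))
  s <- simulate_sift_cohort(co, effects, seed = sift_seed)
  nm <- normalize_sift_matrices(s[c("H3O+", "NO+", "O2+")])
  bl <- lapply(nm, drop_reserved_channels)
  if (block == "h3o") bl[["H3O+"]]
  else combine_precursors(bl[["H3O+"]], bl[["NO+"]], bl[["O2+"]])
}

expect_feature_matrix <- function(fm) {
  testthat::expect_s3_class(fm, "feature_matrix")
  testthat::expect_false(anyNA(fm$values))
}
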