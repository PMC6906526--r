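test_that("cohort generation is deterministic and validates its config", {
  cfg <- cohort_config(n_per_group = 4, seed = 7, effect_scale = 0)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(ages_weeks = c(12, 8)), "increasing")
  expect_error(cohort_config(effect_scale = -1), "effect_scale")
  expect_error(cohort_config(genotypes = character(0)))

  co <- generate_cohort(cfg)
  expect_false(anyDuplicated(co$animals$animal_id) > 0)
  expect_true(all(co$phenotypes$bodyweight_g > 0))
  expect_true(all(co$phenotypes$blood_glucose_mmol_per_L > 0))
})

test_that("phenotype trajectories match the diabetic-model anchors", {
  # het glucose means exceed the hyperglycaemia threshold from 16 weeks
  co <- generate_cohort(cohort_config(n_per_group = 15, seed = 3))
  ph <- merge(co$phenotypes, co$animals, by = "animal_id")
  for (a in c(16, 20)) {
    m <- mean(ph$blood_glucose_mmol_per_L[ph$genotype == "het" &
                                            ph$age_weeks == a])
    expect_gt(m, 11.1)
  }
  expect_lt(mean(ph$blood_glucose_mmol_per_L[ph$genotype == "wt"]), 9)

  # terminal insulin medians near 12 (het) and 2.3 (wt); ceiling at 15
  med_het <- med_wt <- numeric(5)
  ceiling_hit <- 0
  for (k in 1:5) {
    ck <- generate_cohort(cohort_config(n_per_group = 15, seed = 100 + k))
    pk <- merge(ck$phenotypes, ck$animals, by = "animal_id")
    ins <- pk[!is.na(pk$plasma_insulin_ng_per_mL), ]
    med_het[k] <- median(ins$plasma_insulin_ng_per_mL[ins$genotype == "het"])
    med_wt[k] <- median(ins$plasma_insulin_ng_per_mL[ins$genotype == "wt"])
    expect_true(all(ins$plasma_insulin_ng_per_mL <= 15))
    ceiling_hit <- ceiling_hit + sum(ins$plasma_insulin_ng_per_mL == 15)
  }
  expect_true(all(med_het >= 10 & med_het <= 14))
  expect_true(all(med_wt >= 1.5 & med_wt <= 3.5))
  expect_gt(ceiling_hit, 0)  # some het draws get censored at the assay ceiling
})

test_that("a null cohort rejects at about the nominal rate", {
  # two-sample t-test on glucose, het vs wt, effect_scale 0, 200 cohorts
  rej <- 0
  for (k in 1:200) {
    co <- generate_cohort(cohort_config(n_per_group = 10, ages_weeks = 16,
                                        seed = 2000 + k, effect_scale = 0))
    ph <- merge(co$phenotypes, co$animals, by = "animal_id")
    p <- t.test(blood_glucose_mmol_per_L ~ genotype, data = ph)$p.value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.10)
})

test_that("SIFT spectra carry the precursor/hydrate structure", {
  an <- list(animal_id = "het_F_01", genotype = "het")
  sp <- simulate_sift_spectrum(an, 12, noise_seed = 5, humidity = 0.4)
  expect_named(sp, c("H3O+", "NO+", "O2+"))
  h <- sp[["H3O+"]]
  expect_identical(as.integer(names(h$counts)), 10:140)
  expect_true(all(h$counts >= 0))
  # dominant m/z 19 with hydrates scaled by humidity
  expect_gt(h$counts[["19"]], 1e5)
  expect_gt(h$counts[["37"]], h$counts[["55"]])
  expect_gt(h$counts[["55"]], h$counts[["73"]])
  # isotope satellites are small fractions of their parents
  expect_lt(h$counts[["20"]] / h$counts[["19"]], 0.01)
  # NO+/O2+ carry their own reagent peaks
  expect_gt(sp[["NO+"]]$counts[["30"]], 1e5)
  expect_gt(sp[["O2+"]]$counts[["32"]], 1e5)

  # determinism and the dry-sample limit
  expect_identical(sp, simulate_sift_spectrum(an, 12, noise_seed = 5,
                                              humidity = 0.4))
  dry <- simulate_sift_spectrum(an, 12, noise_seed = 5, humidity = 0)[["H3O+"]]
  for (mz in c("37", "55", "73"))
    expect_lt(dry$counts[[mz]] / dry$counts[["19"]], 1e-3)
  expect_error(simulate_sift_spectrum(an, 12, effects = data.frame(
    kind = "sift", precursor = "Xe+", mz = 61L, label = NA, magnitude = 2,
    direction = "up", affected_genotype = "het",
    age_trend = I(list(NULL))), noise_seed = 1), "unknown")
})

test_that("injected fold-changes are recovered in channel means", {
  eff <- sift_effect("H3O+", 61, 3)
  het <- list(animal_id = "h", genotype = "het")
  wt <- list(animal_id = "w", genotype = "wt")
  v_het <- vapply(1:100, function(k)
    simulate_sift_spectrum(het, 12, eff, noise_seed = k)[["H3O+"]]$counts[["61"]],
    numeric(1))
  v_wt <- vapply(1:100, function(k)
    simulate_sift_spectrum(wt, 12, eff, noise_seed = 500 + k)[["H3O+"]]$counts[["61"]],
    numeric(1))
  expect_gt(mean(v_het) / mean(v_wt), 2.5)
  expect_lt(mean(v_het) / mean(v_wt), 3.5)
})

test_that("chromatograms warp jointly and cancel run factors", {
  an <- list(animal_id = "het_F_01", genotype = "het")
  r0 <- simulate_chromatogram(an, 12, drift_seed = 1, drift_amplitude = 0)
  r0b <- simulate_chromatogram(an, 12, drift_seed = 2, drift_amplitude = 0)
  # zero drift: identical retention times across runs
  expect_equal(r0$peaks$peaks$rt_min, r0b$peaks$peaks$rt_min)
  expect_equal(r0$warp_coef, 0)
  expect_error(simulate_chromatogram(an, 12, drift_seed = 1,
                                     drift_amplitude = 10), "monotone")

  # run-level factor cancels under IS normalization
  pt <- r0$peaks
  scaled <- pt
  scaled$peaks$area <- scaled$peaks$area * 3
  expect_equal(normalize_internal_standard(pt)$peaks$area,
               normalize_internal_standard(scaled)$peaks$area)

  # acetic-acid fold-change 2 shows up in normalized areas
  eff <- gcms_effect("Acetic acid", 2)
  wt <- list(animal_id = "w", genotype = "wt")
  get_area <- function(animal, k) {
    run <- simulate_chromatogram(animal, 12, eff, drift_seed = k)
    pk <- normalize_internal_standard(run$peaks)$peaks
    pk$area[pk$label == "Acetic acid"]
  }
  a_het <- vapply(1:100, function(k) get_area(an, k), numeric(1))
  a_wt <- vapply(1:100, function(k) get_area(wt, 300 + k), numeric(1))
  expect_gt(mean(a_het) / mean(a_wt), 1.7)
  expect_lt(mean(a_het) / mean(a_wt), 2.3)
})

test_that("cohort-level writers produce the expected CSV layout", {
  co <- generate_cohort(cohort_config(n_per_group = 2, ages_weeks = c(8, 12),
                                      seed = 1))
  s <- simulate_sift_cohort(co, seed = 2)
  g <- simulate_gcms_cohort(co, seed = 3)
  dir <- tempfile("murivoc")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_cohort(co, dir)
  write_sift_matrices(s, dir)
  write_gcms_runs(g, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "phenotypes.csv")))
  wide <- read.csv(file.path(dir, "sift_h3o.csv"), check.names = FALSE)
  expect_equal(ncol(wide), 1 + 131)   # sample_id + m/z 10..140
  expect_equal(nrow(wide), nrow(co$animals) * 2)
  peaks <- read.csv(file.path(dir, "gcms_peaks.csv"))
  expect_true(all(c("sample_id", "rt_min", "area", "label") %in% names(peaks)))
  tabs <- read_gcms_peaks(file.path(dir, "gcms_peaks.csv"))
  expect_length(tabs, nrow(co$animals) * 2)
})
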