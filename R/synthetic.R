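#' Cohort configuration for the synthetic study generator
#'
#' Describes a longitudinal genotype x sex x age design mirroring a
#' two-genotype mouse study: wild-type (`wt`) littermates against either a
#' Cushing's-type hyperglycaemic mutant (`het`) or a knockout with impaired
#' glucose tolerance (`hom`). `effect_scale` is a dimensionless multiplier
#' on every genotype/age effect: 0 yields a null cohort in which all group
#' differences collapse to sampling noise.
#'
#' @param n_per_group animals per genotype x sex cell (>= 2).
#' @param genotypes subset of `c("wt", "het", "hom")`.
#' @param ages_weeks strictly increasing ages at which phenotypes and
#'   headspace samples are taken. Default `c(8, 12, 16, 20)` (the
#'   heterozygote study design); the knockout design uses `c(8, 12, 16)`.
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @param effect_scale non-negative effect multiplier.
#' @param background strain background label.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 8,
                          genotypes = c("wt", "het"),
                          ages_weeks = c(8, 12, 16, 20),
                          seed = 1L,
                          effect_scale = 1,
                          background = "B6-C3PDE") {
  genotypes <- match.arg(genotypes, c("wt", "het", "hom"), several.ok = TRUE)
  if (length(genotypes) == 0) stop("at least one genotype is required")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (length(ages_weeks) < 1 || any(diff(ages_weeks) <= 0))
    stop("ages_weeks must be strictly increasing")
  if (effect_scale < 0) stop("effect_scale must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 genotypes = genotypes,
                 ages_weeks = as.numeric(ages_weeks),
                 seed = as.integer(seed),
                 effect_scale = effect_scale,
                 background = background),
            class = "cohort_config")
}

# Phenotype mean curves. Deltas are expressed relative to the wild-type
# curve at the same age and sex, and are multiplied by effect_scale.
# Interpolation lets the same curves serve arbitrary age grids.
pheno_curves <- list(
  bodyweight_wt = list(F = list(age = c(8, 12, 16, 20), v = c(19, 22, 24, 25)),
                       M = list(age = c(8, 12, 16, 20), v = c(24, 28, 30, 31))),
  bodyweight_delta = list(
    het = list(F = list(age = c(8, 12, 16, 20), v = c(3, 3, 3, 3)),
               M = list(age = c(8, 12, 16, 20), v = c(2.5, 3, 1, -1))),
    hom = list(F = list(age = c(8, 12, 16), v = c(0, 0, 0)),
               M = list(age = c(8, 12, 16), v = c(0, 0, 0)))),
  glucose_wt = 7.0,
  glucose_delta = list(
    het = list(age = c(8, 12, 16, 20), v = c(1.5, 2.5, 6.0, 7.5)),
    hom = list(age = c(8, 12, 16), v = c(2.0, 2.2, 2.4))),
  insulin_median = list(wt = 2.3, het = 12, hom = 2.3),
  insulin_sdlog = 0.4,
  insulin_ceiling = 15,
  bodyweight_sd_animal = 0.8,
  bodyweight_sd = 0.9,
  glucose_sd = 0.9
)

curve_at <- function(curve, age) {
  stats::approx(curve$age, curve$v, xout = age, rule = 2)$y
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces animals (genotype, sex, background) and per-age phenotype
#' records: bodyweight (piecewise-linear genotype x sex mean curves plus an
#' animal-level random intercept and Gaussian noise), blood glucose
#' (wild-type mean 7.0 mmol/L; the `het` deviation grows with age so that
#' mean glucose exceeds the 11.1 mmol/L hyperglycaemia threshold from 16
#' weeks at `effect_scale = 1`; the `hom` deviation sits in the impaired
#' glucose tolerance band), and terminal-age plasma insulin (log-normal,
#' medians 2.3 ng/mL for `wt` and 12 ng/mL for `het` at `effect_scale = 1`,
#' right-censored at the 15 ng/mL assay ceiling).
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort` with data frames `animals`
#'   (`animal_id`, `genotype`, `sex`, `background`) and `phenotypes`
#'   (long format: `animal_id`, `age_weeks`, `bodyweight_g`,
#'   `blood_glucose_mmol_per_L`, `plasma_insulin_ng_per_mL` — insulin is
#'   `NA` except at the terminal age).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  es <- config$effect_scale
  ages <- config$ages_weeks
  terminal <- max(ages)

  grid <- expand.grid(sex = c("F", "M"), genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  animals <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$genotype[i]; s <- grid$sex[i]
    data.frame(
      animal_id = sprintf("%s_%s_%02d", g, s, seq_len(config$n_per_group)),
      genotype = g, sex = s, background = config$background,
      stringsAsFactors = FALSE)
  }))
  rownames(animals) <- NULL

  phen <- with_seed(derive_seed(config$seed, 1L), {
    bw_intercept <- rnorm(nrow(animals), 0, pheno_curves$bodyweight_sd_animal)
    recs <- lapply(seq_len(nrow(animals)), function(i) {
      g <- animals$genotype[i]; s <- animals$sex[i]
      bw_mean <- curve_at(pheno_curves$bodyweight_wt[[s]], ages)
      gl_mean <- rep(pheno_curves$glucose_wt, length(ages))
      if (g != "wt") {
        bw_mean <- bw_mean +
          es * curve_at(pheno_curves$bodyweight_delta[[g]][[s]], ages)
        gl_mean <- gl_mean + es * curve_at(pheno_curves$glucose_delta[[g]], ages)
      }
      bw <- pmax(bw_mean + bw_intercept[i] +
                   rnorm(length(ages), 0, pheno_curves$bodyweight_sd), 0.1)
      gl <- pmax(gl_mean + rnorm(length(ages), 0, pheno_curves$glucose_sd), 0.1)
      mlog_wt <- log(pheno_curves$insulin_median$wt)
      mlog_g <- log(pheno_curves$insulin_median[[g]])
      ins_mlog <- mlog_wt + es * (mlog_g - mlog_wt)
      ins <- rlnorm(1, ins_mlog, pheno_curves$insulin_sdlog)
      ins <- min(ins, pheno_curves$insulin_ceiling)
      data.frame(animal_id = animals$animal_id[i], age_weeks = ages,
                 bodyweight_g = bw, blood_glucose_mmol_per_L = gl,
                 plasma_insulin_ng_per_mL = ifelse(ages == terminal, ins, NA),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  rownames(phen) <- NULL
  structure(list(animals = animals, phenotypes = phen, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d animals (%s), ages %s weeks\n",
              nrow(x$animals), paste(unique(x$animals$genotype), collapse = "/"),
              paste(x$config$ages_weeks, collapse = "/")))
  invisible(x)
}

#' Effect specifications for the spectral generators
#'
#' An effect is a multiplicative fold-change on the mean signal of one
#' channel (SIFT-MS precursor + m/z) or one GC-MS compound, applied in the
#' affected genotype, optionally modulated across ages. The realized fold is
#' `magnitude^(effect_scale * trend)` (inverted for `direction = "down"`),
#' so `effect_scale = 0` is exactly the null and fold-changes compose
#' log-linearly.
#'
#' @param precursor one of `"H3O+"`, `"NO+"`, `"O2+"`.
#' @param mz integer m/z channel in 10..140.
#' @param label GC-MS compound label (matched against peak labels).
#' @param magnitude fold-change > 0 (on the scale of the affected group mean).
#' @param direction `"up"` or `"down"` in the affected genotype.
#' @param affected_genotype genotype carrying the effect.
#' @param age_trend optional named numeric vector of per-age exponents
#'   (names are ages in weeks); ages not listed use 1.
#' @return A one-row data frame (effects tables are built by `rbind`).
#' @export
sift_effect <- function(precursor, mz, magnitude, direction = "up",
                        affected_genotype = "het", age_trend = NULL) {
  if (!precursor %in% c("H3O+", "NO+", "O2+")) stop("unknown precursor")
  if (mz < 10 || mz > 140) stop("m/z must be in [10, 140]")
  if (magnitude <= 0) stop("magnitude must be > 0")
  direction <- match.arg(direction, c("up", "down"))
  out <- data.frame(kind = "sift", precursor = precursor, mz = as.integer(mz),
                    label = NA_character_, magnitude = magnitude,
                    direction = direction,
                    affected_genotype = affected_genotype,
                    stringsAsFactors = FALSE)
  out$age_trend <- list(age_trend)
  out
}

#' @rdname sift_effect
#' @export
gcms_effect <- function(label, magnitude, direction = "up",
                        affected_genotype = "het", age_trend = NULL) {
  if (magnitude <= 0) stop("magnitude must be > 0")
  direction <- match.arg(direction, c("up", "down"))
  out <- data.frame(kind = "gcms", precursor = NA_character_, mz = NA_integer_,
                    label = label, magnitude = magnitude,
                    direction = direction,
                    affected_genotype = affected_genotype,
                    stringsAsFactors = FALSE)
  out$age_trend <- list(age_trend)
  out
}

#' Default effect panels
#'
#' The default SIFT-MS panel places genotype effects on the H3O+ channels
#' repeatedly reported as discriminatory for the hyperglycaemic mutant
#' (m/z 47 ethanol/formic acid, 59 acetone/propanol, 61 and 79 acetic
#' acid/propanol, 65 ethanol, 77 acetone, 89 butyric acid — reduced in the
#' mutant — and O2+ 31, a methanol/ethanol by-product), plus an age trend
#' on the acetone-related channels. The GC-MS panel mirrors the compound
#' table: acetone, 2,3-butanedione, acetic acid and propanoic acid ethyl
#' ester elevated; the butyric esters reduced.
#'
#' @param magnitude base fold-change for every effect (default 2).
#' @return An effects data frame (one row per affected channel/compound).
#' @export
default_sift_effects <- function(magnitude = 2) {
  acetone_trend <- c(`8` = 0.7, `12` = 0.9, `16` = 1.2, `20` = 1.5)
  rbind(
    sift_effect("H3O+", 47, magnitude, "up"),
    sift_effect("H3O+", 59, magnitude, "up", age_trend = acetone_trend),
    sift_effect("H3O+", 61, magnitude, "up"),
    sift_effect("H3O+", 65, magnitude, "up"),
    sift_effect("H3O+", 77, magnitude, "up", age_trend = acetone_trend),
    sift_effect("H3O+", 79, magnitude, "up"),
    sift_effect("H3O+", 89, magnitude, "down"),
    sift_effect("O2+", 31, magnitude, "up"))
}

#' @rdname default_sift_effects
#' @export
default_gcms_effects <- function(magnitude = 2) {
  rbind(
    gcms_effect("Acetone", magnitude, "up",
                age_trend = c(`8` = 0.7, `12` = 0.9, `16` = 1.2, `20` = 1.5)),
    gcms_effect("2,3-Butanedione", magnitude, "up"),
    gcms_effect("Acetic acid", magnitude, "up"),
    gcms_effect("Propanoic acid, ethyl ester", magnitude, "up"),
    gcms_effect("Butyric acid, ethyl ester", magnitude, "down"),
    gcms_effect("Butyric acid, 2-methyl", magnitude, "down"))
}

# Realized fold multiplier for one sample on one effect row.
effect_fold <- function(eff, genotype, age_weeks, effect_scale) {
  if (!identical(eff$affected_genotype, genotype)) return(1)
  trend <- 1
  tr <- eff$age_trend[[1]]
  if (!is.null(tr)) {
    hit <- match(as.character(age_weeks), names(tr))
    if (!is.na(hit)) trend <- tr[[hit]]
  }
  base <- if (eff$direction == "up") eff$magnitude else 1 / eff$magnitude
  base^(effect_scale * trend)
}

# Generator constants for SIFT-MS spectra.
sift_gen <- list(
  mz = 10:140,
  precursor_total = 1e6,       # cps distributed over precursor + hydrates
  baseline_mean = 50,          # cps, unremarkable channels
  signal_mean = 200,           # cps, channels carrying biological signal
  sdlog = 0.3,                 # multiplicative log-normal noise
  poisson_baseline = 5,        # additive counting noise
  run_sdlog = 0.2,             # per-acquisition global intensity factor
  hydrate_weights = c(`37` = 0.5, `55` = 0.3, `73` = 0.2),
  iso1_frac = 4e-4,            # (m/z + 1) satellite, 17O-like
  iso2_frac = 2e-3             # (m/z + 2) satellite, 18O-like
)

#' Simulate one animal's SIFT-MS full-scan spectra
#'
#' Generates count-rate spectra over integer m/z 10..140 for the three
#' precursor ions. The H3O+ spectrum carries the precursor peak at m/z 19
#' together with hydrate cluster ions at m/z 37/55/73 whose share of the
#' total precursor intensity is set by `humidity` (0 routes everything to
#' m/z 19), and small isotope satellites at +1/+2 of each cluster peak.
#' NO+ and O2+ carry their precursor peaks at m/z 30 and 32 with the same
#' satellite structure. Analyte channels are drawn from a log-normal model
#' around genotype/age-dependent means (multiplied by the realized effect
#' folds) plus additive Poisson counting noise; a per-acquisition global
#' intensity factor multiplies the whole spectrum triple.
#'
#' @param animal one-row data frame or list with at least `animal_id` and
#'   `genotype`.
#' @param age_weeks sampling age.
#' @param effects effects table ([default_sift_effects()] by default).
#' @param noise_seed integer seed; identical seeds give identical spectra.
#' @param humidity latent humidity in `[0, 1]`.
#' @param effect_scale effect multiplier (see [cohort_config()]).
#' @return Named list of three [sift_spectrum()] objects
#'   (`"H3O+"`, `"NO+"`, `"O2+"`).
#' @export
simulate_sift_spectrum <- function(animal, age_weeks,
                                   effects = default_sift_effects(),
                                   noise_seed = 1L, humidity = 0.3,
                                   effect_scale = 1) {
  if (humidity < 0 || humidity > 1) stop("humidity must be in [0, 1]")
  effects <- effects[effects$kind == "sift", , drop = FALSE]
  if (nrow(effects) > 0 &&
      (any(!effects$precursor %in% c("H3O+", "NO+", "O2+")) ||
       any(effects$mz < 10 | effects$mz > 140)))
    stop("unknown effect key (precursor/mz)")

  mz <- sift_gen$mz
  sample_id <- sprintf("%s_w%02d", animal$animal_id, as.integer(age_weeks))

  with_seed(noise_seed, {
    run_factor <- rlnorm(1, 0, sift_gen$run_sdlog)
    out <- lapply(c("H3O+", "NO+", "O2+"), function(prec) {
      mean_vec <- rep(sift_gen$baseline_mean, length(mz))
      names(mean_vec) <- mz
      pe <- effects[effects$precursor == prec, , drop = FALSE]
      # channels carrying signal get the higher base mean regardless of
      # whether this animal's genotype is affected
      mean_vec[as.character(pe$mz)] <- sift_gen$signal_mean
      if (nrow(pe) > 0) {
        for (k in seq_len(nrow(pe))) {
          f <- effect_fold(pe[k, ], animal$genotype, age_weeks, effect_scale)
          ch <- as.character(pe$mz[k])
          mean_vec[ch] <- mean_vec[ch] * f
        }
      }
      counts <- rlnorm(length(mz), log(mean_vec) - sift_gen$sdlog^2 / 2,
                       sift_gen$sdlog) +
        rpois(length(mz), sift_gen$poisson_baseline)
      names(counts) <- mz

      # precursor / hydrate-cluster structure
      parents <- if (prec == "H3O+") {
        hw <- sift_gen$hydrate_weights * humidity
        c(`19` = 1 - humidity, hw) * sift_gen$precursor_total
      } else {
        pm <- as.character(precursor_mz(prec))
        setNames(sift_gen$precursor_total, pm)
      }
      for (pm in names(parents)) {
        v <- parents[[pm]]
        i <- as.integer(pm)
        counts[as.character(i)] <- counts[as.character(i)] + v
        counts[as.character(i + 1)] <-
          counts[as.character(i + 1)] + v * sift_gen$iso1_frac
        counts[as.character(i + 2)] <-
          counts[as.character(i + 2)] + v * sift_gen$iso2_frac
      }
      sift_spectrum(sample_id, prec, counts * run_factor)
    })
    names(out) <- c("H3O+", "NO+", "O2+")
    out
  })
}

# Generator constants for GC-MS runs. RTs follow the discriminatory-compound
# table (minutes); CAS numbers are carried as labels only. Mean areas are
# generator parameters (arbitrary units).
gcms_gen <- list(
  compounds = data.frame(
    rt_min = c(4.277, 6.585, 9.707, 10.861, 12.011, 12.244, 15.074),
    mean_area = c(4e4, 5e5, 8e4, 3e5, 1e5, 9e4, 6e4),
    label = c("Unknown", "Acetone", "2,3-Butanedione", "Acetic acid",
              "Propanoic acid, ethyl ester", "Butyric acid, ethyl ester",
              "Butyric acid, 2-methyl"),
    cas = c(NA, "67-64-1", "431-03-8", "64-19-7", "105-37-3", "105-54-4",
            "116-53-0"),
    stringsAsFactors = FALSE),
  is_rt = 8.90, is_area = 2e5, is_label = "d8-toluene (IS)",
  peak_sigma = 0.04,           # minutes
  area_sdlog = 0.25,           # per-peak multiplicative noise
  run_sdlog = 0.25,            # run-level intensity factor (hits IS too)
  run_length = 18, rt_step = 0.01
)

#' Simulate one GC-MS run (peak table + dense trace)
#'
#' Compounds are Gaussian peaks at fixed nominal retention times; each run
#' carries a d8-toluene internal-standard peak and a run-level intensity
#' factor multiplying every area (so internal-standard normalization
#' cancels it exactly). A smooth monotone RT warp
#' `rt + a sin(pi rt / L)`, `a ~ U(-amplitude, amplitude)`, displaces all
#' peaks jointly; correlation optimised warping is designed to undo it.
#'
#' @inheritParams simulate_sift_spectrum
#' @param drift_seed integer seed for this run.
#' @param drift_amplitude maximal warp displacement in minutes (default
#'   0.15); must keep the warp monotone (`amplitude * pi / L < 1`).
#' @return List with `peaks` (a [peak_table()]), `trace` (data frame
#'   `rt_min`, `intensity` on the run's RT grid) and `warp_coef` (the drawn
#'   warp coefficient, minutes).
#' @export
simulate_chromatogram <- function(animal, age_weeks,
                                  effects = default_gcms_effects(),
                                  drift_seed = 1L, drift_amplitude = 0.15,
                                  effect_scale = 1) {
  L <- gcms_gen$run_length
  if (drift_amplitude * pi / L >= 1)
    stop("drift_amplitude makes the retention-time warp non-monotone")
  effects <- effects[effects$kind == "gcms", , drop = FALSE]
  sample_id <- sprintf("%s_w%02d", animal$animal_id, as.integer(age_weeks))

  with_seed(drift_seed, {
    a <- runif(1, -drift_amplitude, drift_amplitude)
    run_factor <- rlnorm(1, 0, gcms_gen$run_sdlog)
    comp <- gcms_gen$compounds
    fold <- vapply(seq_len(nrow(comp)), function(i) {
      hit <- which(effects$label == comp$label[i])
      if (length(hit) == 0) return(1)
      effect_fold(effects[hit[1], ], animal$genotype, age_weeks, effect_scale)
    }, numeric(1))
    areas <- comp$mean_area * fold *
      rlnorm(nrow(comp), -gcms_gen$area_sdlog^2 / 2, gcms_gen$area_sdlog)
    warp <- function(rt) rt + a * sin(pi * rt / L)
    rt_obs <- warp(comp$rt_min)
    is_rt_obs <- warp(gcms_gen$is_rt)
    is_area <- gcms_gen$is_area *
      rlnorm(1, -gcms_gen$area_sdlog^2 / 2, gcms_gen$area_sdlog)

    peaks <- data.frame(
      rt_min = c(rt_obs, is_rt_obs),
      area = c(areas, is_area) * run_factor,
      label = c(comp$label, gcms_gen$is_label),
      stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$rt_min), ]
    rownames(peaks) <- NULL

    grid <- seq(0, L, by = gcms_gen$rt_step)
    intensity <- rep(0, length(grid))
    for (i in seq_len(nrow(peaks)))
      intensity <- intensity + peaks$area[i] *
        exp(-(grid - peaks$rt_min[i])^2 / (2 * gcms_gen$peak_sigma^2))

    list(peaks = peak_table(sample_id, peaks,
                            internal_standard_label = gcms_gen$is_label),
         trace = data.frame(rt_min = grid, intensity = intensity),
         warp_coef = a)
  })
}

#' Simulate headspace acquisitions for a whole cohort
#'
#' One acquisition per animal per age. `simulate_sift_cohort` returns the
#' three per-precursor raw count matrices as [feature_matrix()] objects
#' (features `"<precursor>:<mz>"`) plus the per-sample humidity draws;
#' `simulate_gcms_cohort` returns per-run peak tables and dense traces.
#'
#' @param cohort a [generate_cohort()] result.
#' @param effects effects table.
#' @param seed integer master seed (per-acquisition seeds are derived).
#' @param humidity_mean,humidity_sd per-sample humidity latent (clamped to
#'   `[0.02, 0.98]`).
#' @return See description.
#' @export
simulate_sift_cohort <- function(cohort, effects = default_sift_effects(),
                                 seed = 1L, humidity_mean = 0.3,
                                 humidity_sd = 0.05) {
  es <- cohort$config$effect_scale
  ages <- cohort$config$ages_weeks
  idx <- expand.grid(ai = seq_len(nrow(cohort$animals)), age = ages)
  hum <- with_seed(derive_seed(seed, 2L),
                   pmin(pmax(rnorm(nrow(idx), humidity_mean, humidity_sd),
                             0.02), 0.98))
  spectra <- lapply(seq_len(nrow(idx)), function(i) {
    an <- cohort$animals[idx$ai[i], ]
    simulate_sift_spectrum(an, idx$age[i], effects,
                           noise_seed = derive_seed(seed, 10L + i),
                           humidity = hum[i], effect_scale = es)
  })
  meta <- data.frame(
    sample_id = vapply(spectra, function(s) s[["H3O+"]]$sample_id, ""),
    animal_id = cohort$animals$animal_id[idx$ai],
    genotype = cohort$animals$genotype[idx$ai],
    sex = cohort$animals$sex[idx$ai],
    age_weeks = idx$age, humidity = hum,
    stringsAsFactors = FALSE)
  mats <- lapply(c("H3O+", "NO+", "O2+"), function(prec) {
    vals <- do.call(rbind, lapply(spectra, function(s) s[[prec]]$counts))
    rownames(vals) <- meta$sample_id
    colnames(vals) <- paste0(prec, ":", sift_gen$mz)
    feature_matrix(vals, meta)
  })
  names(mats) <- c("H3O+", "NO+", "O2+")
  c(mats, list(spectra = spectra, metadata = meta))
}

#' @rdname simulate_sift_cohort
#' @param drift_amplitude RT warp amplitude in minutes.
#' @export
simulate_gcms_cohort <- function(cohort, effects = default_gcms_effects(),
                                 seed = 1L, drift_amplitude = 0.15) {
  es <- cohort$config$effect_scale
  ages <- cohort$config$ages_weeks
  idx <- expand.grid(ai = seq_len(nrow(cohort$animals)), age = ages)
  runs <- lapply(seq_len(nrow(idx)), function(i) {
    an <- cohort$animals[idx$ai[i], ]
    simulate_chromatogram(an, idx$age[i], effects,
                          drift_seed = derive_seed(seed, 20L + i),
                          drift_amplitude = drift_amplitude,
                          effect_scale = es)
  })
  meta <- data.frame(
    sample_id = vapply(runs, function(r) r$peaks$sample_id, ""),
    animal_id = cohort$animals$animal_id[idx$ai],
    genotype = cohort$animals$genotype[idx$ai],
    sex = cohort$animals$sex[idx$ai],
    age_weeks = idx$age, stringsAsFactors = FALSE)
  list(tables = lapply(runs, `[[`, "peaks"),
       traces = lapply(runs, `[[`, "trace"),
       warp_coefs = vapply(runs, `[[`, numeric(1), "warp_coef"),
       metadata = meta)
}

#' Write cohort and acquisition tables as CSV
#'
#' Writers for the generator outputs: `cohort.csv`, `phenotypes.csv`,
#' `sift_<precursor>.csv` (wide, one column per m/z), `gcms_peaks.csv`
#' (long) and `gcms_trace_<sample>.csv`.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "cohort.csv")
  p2 <- file.path(dir, "phenotypes.csv")
  write.csv(cohort$animals, p1, row.names = FALSE)
  write.csv(cohort$phenotypes, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_cohort
#' @param sift result of [simulate_sift_cohort()].
#' @export
write_sift_matrices <- function(sift, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("H3O+", "NO+", "O2+"), function(prec) {
    tag <- c(`H3O+` = "h3o", `NO+` = "no", `O2+` = "o2")[[prec]]
    path <- file.path(dir, sprintf("sift_%s.csv", tag))
    write_feature_matrix(sift[[prec]], path)
    path
  }, "")
  invisible(paths)
}

#' @rdname write_cohort
#' @param gcms result of [simulate_gcms_cohort()].
#' @export
write_gcms_runs <- function(gcms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peaks <- do.call(rbind, lapply(gcms$tables, function(pt) {
    data.frame(sample_id = pt$sample_id, pt$peaks, stringsAsFactors = FALSE)
  }))
  p <- file.path(dir, "gcms_peaks.csv")
  write.csv(peaks, p, row.names = FALSE)
  tr <- vapply(seq_along(gcms$traces), function(i) {
    path <- file.path(dir, sprintf("gcms_trace_%s.csv",
                                   gcms$metadata$sample_id[i]))
    write.csv(gcms$traces[[i]], path, row.names = FALSE)
    path
  }, "")
  invisible(c(p, tr))
}
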