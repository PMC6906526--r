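#' Univariate group comparison with the study's test-selection map
#'
#' Dispatches on design and distributional assumption, mirroring common
#' phenotyping practice: (independent, normal) two-sample t-test (Welch by
#' default); (independent, free) Mann-Whitney U (exact for combined
#' n <= 20 without ties, normal approximation with tie correction
#' otherwise); (repeated, normal) one-way repeated-measures ANOVA with
#' Bonferroni-adjusted pairwise paired t-tests; (repeated, free) Friedman
#' test with Bonferroni-adjusted pairwise Wilcoxon signed-rank tests.
#' Normality is a caller-declared attribute — there is no automatic
#' normality testing. All tests are two-sided.
#'
#' @param values numeric measurements.
#' @param groups group/condition labels (>= 2 groups, each >= 2 values).
#' @param design `"independent"` or `"repeated"`.
#' @param distribution `"normal"` or `"free"`.
#' @param subject subject identifiers (required for `design = "repeated"`;
#'   blocks must be complete).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return A `test_result`: `test`, `statistic`, `p_value`, `n_per_group`,
#'   `direction` (sign of group-2-minus-group-1 location for two groups),
#'   and for repeated designs `posthoc` (pairwise comparisons with
#'   Bonferroni-adjusted p-values).
#' @export
compare_groups <- function(values, groups,
                           design = c("independent", "repeated"),
                           distribution = c("normal", "free"),
                           subject = NULL, var_equal = FALSE) {
  design <- match.arg(design)
  distribution <- match.arg(distribution)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 values")
  npg <- as.list(table(groups))

  direction <- NA_character_
  if (length(lv) == 2) {
    d <- median(values[groups == lv[2]]) - median(values[groups == lv[1]])
    direction <- if (d > 0) "up" else if (d < 0) "down" else "none"
  }

  if (design == "independent") {
    if (length(lv) != 2)
      stop("independent designs support two groups here")
    a <- values[groups == lv[1]]; b <- values[groups == lv[2]]
    if (distribution == "normal") {
      ht <- t.test(a, b, var.equal = var_equal)
      res <- list(test = if (var_equal) "t-test (pooled)" else "t-test (Welch)",
                  statistic = unname(ht$statistic), p_value = ht$p.value)
    } else {
      exact <- (length(a) + length(b)) <= 20 && !any(duplicated(values))
      ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
      res <- list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
                  p_value = ht$p.value)
    }
    posthoc <- NULL
  } else {
    if (is.null(subject)) stop("repeated design requires `subject`")
    subject <- as.character(subject)
    blocks <- table(subject, groups)
    if (any(blocks != 1))
      stop("repeated design requires complete blocks (one value per subject per condition)")
    df <- data.frame(y = values, g = factor(groups), s = factor(subject))
    if (distribution == "normal") {
      fit <- aov(y ~ g + Error(s), data = df)
      st <- summary(fit)[["Error: Within"]][[1]]
      res <- list(test = "repeated-measures ANOVA",
                  statistic = st[["F value"]][1], p_value = st[["Pr(>F)"]][1])
      ph <- pairwise_repeated(df, paired_test = "t")
    } else {
      ht <- friedman.test(y ~ g | s, data = df)
      stat <- unname(ht$statistic); pv <- ht$p.value
      if (is.nan(stat)) {   # all conditions tied within every subject
        stat <- 0; pv <- 1
      }
      res <- list(test = "Friedman", statistic = stat, p_value = pv)
      ph <- pairwise_repeated(df, paired_test = "wilcoxon")
    }
    posthoc <- ph
  }
  structure(c(res, list(n_per_group = npg, direction = direction,
                        posthoc = posthoc, design = design,
                        distribution = distribution)),
            class = "test_result")
}

# Bonferroni-adjusted pairwise paired comparisons across conditions.
pairwise_repeated <- function(df, paired_test) {
  lv <- levels(df$g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  raw <- vapply(pairs, function(pr) {
    wide <- merge(df[df$g == pr[1], c("s", "y")],
                  df[df$g == pr[2], c("s", "y")], by = "s")
    # zero-variance paired differences leave the test statistic undefined
    tryCatch({
      if (paired_test == "t")
        t.test(wide$y.x, wide$y.y, paired = TRUE)$p.value
      else
        suppressWarnings(wilcox.test(wide$y.x, wide$y.y, paired = TRUE,
                                     exact = nrow(wide) <= 20 &&
                                       !any(wide$y.x == wide$y.y))$p.value)
    }, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(group_a = vapply(pairs, `[`, "", 1),
             group_b = vapply(pairs, `[`, "", 2),
             p_raw = raw,
             p_adjusted = bonferroni(raw, length(raw)),
             stringsAsFactors = FALSE)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)`, monotone and capped at 1.
#'
#' @param p raw p-values.
#' @param family_size family size (>= number of p-values).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, family_size = length(p)) {
  if (family_size < 1) stop("family_size must be >= 1")
  if (family_size < length(p)) stop("family_size must be >= number of p-values")
  pmin(1, p * family_size)
}

# Diagnostic thresholds (blood glucose, mmol/L; plasma insulin, ng/mL).
diabetes_thresholds <- list(hyperglycaemia = 11.1, igt_lower = 7.8,
                            insulin_ceiling = 15)

#' Phenotype summaries and diabetes flags
#'
#' Per genotype x sex x age cell: mean and median bodyweight and blood
#' glucose. Per record: a hyperglycaemia flag (glucose > 11.1 mmol/L) and
#' an impaired-glucose-tolerance flag (7.8 <= glucose < 11.1 mmol/L,
#' inclusive lower bound); counts of insulin measurements sitting at the
#' 15 ng/mL assay ceiling.
#'
#' @param cohort a [generate_cohort()] result (or any list with `animals`
#'   and `phenotypes` in the same shape).
#' @return List: `cells` (summary data frame), `flags` (per record),
#'   `insulin_at_ceiling` (count), `insulin_median` (per genotype,
#'   terminal age).
#' @export
phenotype_summary <- function(cohort) {
  ph <- merge(cohort$phenotypes, cohort$animals, by = "animal_id")
  th <- diabetes_thresholds
  flags <- data.frame(
    animal_id = ph$animal_id, age_weeks = ph$age_weeks,
    hyperglycaemic = ph$blood_glucose_mmol_per_L > th$hyperglycaemia,
    igt = ph$blood_glucose_mmol_per_L >= th$igt_lower &
      ph$blood_glucose_mmol_per_L < th$hyperglycaemia,
    stringsAsFactors = FALSE)
  cells <- aggregate(
    cbind(bodyweight_g, blood_glucose_mmol_per_L) ~ genotype + sex + age_weeks,
    data = ph, FUN = function(v) c(mean = mean(v), median = median(v)))
  cells <- do.call(data.frame, cells)
  ins <- ph[!is.na(ph$plasma_insulin_ng_per_mL), ]
  insulin_median <- tapply(ins$plasma_insulin_ng_per_mL, ins$genotype, median)
  list(cells = cells, flags = flags,
       insulin_at_ceiling = sum(ins$plasma_insulin_ng_per_mL >=
                                  th$insulin_ceiling),
       insulin_median = insulin_median)
}
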