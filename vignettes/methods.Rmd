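---
title: "Discriminating mouse genotypes from volatile faecal metabolomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating mouse genotypes from volatile faecal metabolomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murivoc)
```

## The analysis problem

Volatile organic compounds (VOCs) emitted from faecal headspace reflect
gut-microbial fermentation. In mouse models of type 2 diabetes the VOC
profile shifts — short-chain fatty acids (acetic, propionic, butyric acid),
ketones (acetone, 2,3-butanedione) and alcohols are repeatedly reported as
the discriminating compounds. `murivoc` implements the full analysis chain
for a longitudinal two-genotype study (wild-type littermates against a
hyperglycaemic Cushing's-type mutant `het`, or an *Afmid*-knockout-type
`hom` with impaired glucose tolerance): preprocessing of SIFT-MS full-scan
spectra and TD-GC-MS peak tables, multivariate discrimination, resampling
validation, and the univariate phenotype statistics that establish the
diabetic phenotype itself.

No real dataset ships with the package. Instead a synthetic-data module
generates cohorts, phenotype trajectories, SIFT-MS spectra and GC-MS runs
with the statistical structure the analysis assumes, so every stage is
testable end to end. The generator is first-class, tested code: its
defaults define the study conditions under which all package-level
guarantees (null calibration, power, determinism) are stated.

## The synthetic cohort

`cohort_config()` fixes the design: genotype x sex cells of `n_per_group`
animals sampled at ages 8/12/16/20 weeks (8/12/16 for the `hom` design).
A single `effect_scale` multiplies every genotype effect; 0 gives an
exact null cohort.

Phenotype trajectories are piecewise-linear mean curves per genotype and
sex with Gaussian noise:

* **Bodyweight** — wild-type females 19→25 g, males 24→31 g over the
  study; `het` females +3 g throughout, `het` males heavier early with a
  decline after 16 weeks (the glucose-driven weight loss seen in this
  model); animal-level random intercept (sd 0.8 g) plus residual sd 0.9 g.
* **Blood glucose** — wild-type mean 7.0 mmol/L (sd 0.9) at all ages.
  The `het` deviation grows from +1.5 at 8 weeks to +7.5 mmol/L at 20
  weeks, so mean glucose crosses the 11.1 mmol/L hyperglycaemia threshold
  between 12 and 16 weeks; the `hom` deviation is ~+2 mmol/L at all ages,
  inside the impaired-glucose-tolerance band [7.8, 11.1).
* **Plasma insulin** — measured once, at the terminal age, log-normal with
  sdlog 0.4 and medians 2.3 ng/mL (wild-type) and 12 ng/mL (`het`);
  values above the 15 ng/mL assay range are assigned 15, reproducing the
  ELISA ceiling. The `hom` model leaves insulin at wild-type levels.

The paper-reported phenotypes give medians and thresholds but no
per-group variances, so all noise scales above are free generator
parameters chosen once as plausible for these assays; they are not
estimates of the real study's variances.

**SIFT-MS spectra** are integer m/z 10–140 count-rate vectors for the
three precursor ions. Analyte channels are log-normal (sdlog 0.3) around
per-channel means — 50 cps baseline, 200 cps for channels carrying
biological signal — plus Poisson counting noise (mean 5 cps). Genotype
effects multiply the affected channel's mean by
`magnitude^(effect_scale * age_trend)`, so fold-changes compose
log-linearly and `effect_scale = 0` is exactly the null. The H3O+
spectrum carries 10^6 cps of reagent-ion intensity split between m/z 19
and the hydrate cluster ions 37/55/73 by a per-sample humidity latent in
[0, 1] (hydrates split 0.5/0.3/0.2); every cluster peak gets +1 and +2
isotope satellites at 0.04% and 0.2% of the parent. These satellite
fractions are bookkeeping values — small and detectable — not natural
abundances; no real ion-chemistry branching is modelled. A per-acquisition
log-normal factor (sdlog 0.2) multiplies the whole spectrum triple and is
exactly cancelled by precursor normalization.

**GC-MS runs** place Gaussian peaks (sd 0.04 min) at the retention times
of the discriminating compounds (acetone 6.585 min, 2,3-butanedione
9.707, acetic acid 10.861, propanoic acid ethyl ester 12.011, butyric
acid ethyl ester 12.244, 2-methylbutyric acid 15.074, plus one unknown at
4.277); mean areas are generator parameters. Each run carries a
d8-toluene internal standard and a run-level intensity factor (sdlog
0.25) hitting every peak, cancelled by internal-standard normalization.
A smooth monotone warp `rt + a·sin(pi·rt/L)` with `a ~ U(-0.15, 0.15)`
minutes displaces all retention times jointly; correlation optimised
warping is designed to undo exactly this kind of drift.

What the generator does **not** emulate: real spectral cross-talk between
compounds and channels, mass-spectral fragmentation, retention-time
co-elution, heteroscedastic detector saturation, and correlated
within-animal repeated measures in the VOC signal. Passing tests
therefore demonstrate correctness of the computational pipeline under a
clean multiplicative signal model, not performance on real instrument
data.

## Preprocessing

**SIFT-MS.** Counts are normalized to the precursor-ion count rate of the
same acquisition. The text convention names only H3O+ m/z 19, but NO+ and
O2+ spectra contain no H3O+ counts, and m/z 30/32 appear in the
reserved-channel list as reagent ions — so the default normalizes each
spectrum to its own reagent channel (19/30/32), with
`reference = "h3o19"` available to force the single-reference scheme.
Humidity diagnostics (`humidity_fractions()`) report the per-sample
fraction of counts over the 12 hydrate/isotopologue channels and flag
group pairs whose averages differ by more than an order of magnitude;
flags are advisory and never remove samples. The 14 reserved channels
(19, 21, 30, 32, 34, 37, 39, 48, 55, 57, 66, 73, 75, 91) are removed from
every precursor block before multivariate analysis — except on the
LDA/canonical path, which keeps them — taking a full H3O+ block from 131
to 117 channels; the three blocks concatenate to one 351-channel dataset.
For LDA the variables are square-root transformed and standardized
(sample sd, n−1); additional AS/RS/NRM scalings follow their usual
definitions.

**GC-MS.** Areas are divided by the internal-standard area (QC flag, not
removal, when the IS is missing or zero). Dense traces are aligned by
correlation optimised warping: the reference is cut into segments of
nominally 30 points, and a dynamic program places the matching sample
boundaries, each segment allowed to stretch or shrink by up to 3 points
(`slack`), maximizing the summed Pearson correlation of linearly
interpolated segments. Segment length and slack are unreported in typical
method sections; 30/3 are conventional values and both are arguments.
Correlation of an all-constant segment is defined as 0 so flat baseline
neither rewards nor punishes warping, and among equal-score paths the one
with minimal cumulative |stretch| is returned — a deterministic,
minimal-deformation tie-break. Warping applies to dense traces only;
peak-only data skip COW (`build_gcms_matrix()` works directly on peak
tables). Features are assembled by single-linkage clustering of peak
retention times within 0.1 min; a consequence worth knowing is that under
±0.15 min drift two compounds ~0.23 min apart can chain into one feature
across many runs — aligning traces first and re-extracting peaks avoids
this.

## Models

`pca_fit()` wraps the standard centred principal-component decomposition
for outlier screening (Hotelling T² on the retained scores against an
F-distribution cutoff; flags only) and for feature selection: features
are ranked by their maximum absolute loading across the components
covering 90% of variance. Selection is meaningful on raw (centred,
unscaled) intensities, where spectral variance concentrates on
high-signal channels; after autoscaling the eigenvalue spectrum is nearly
flat and the ranking carries no information — the resampling protocol
therefore applies selection before in-fold autoscaling.

`lda_fit()` solves the canonical discriminant eigenproblem through a
symmetric reduction by the within-groups scatter's inverse square root,
using a pseudo-inverse (relative tolerance 1e-10) when within-scatter is
singular (more channels than samples). Directions are scaled to unit
pooled within-class variance; classification is nearest centroid in
canonical space with equal priors (the study design is balanced;
proportional priors would be the alternative convention) and ties break
to the lexicographically smaller label. A known limitation of the
pseudo-inverse route: directions with *zero* within-class variance lie in
the discarded null space, so a feature that separates classes perfectly
with no scatter is invisible to this LDA — the PLS-DA path handles that
case.

`pls_fit()` is NIPALS partial least squares (tolerance 1e-12 on the score
vector, at most 500 iterations per latent variable; for the univariate
and two-class dummy responses used here it converges in one step).
The discriminant wrapper codes classes as one {0,1} dummy column each —
two columns even for two classes, keeping the argmax symmetric — and
predicts by argmax with the same lexicographic tie rule. The compiled
core exists because the validation protocols fit on the order of 10^5
PLS models; an independent Krylov-subspace closed form serves as the
oracle in the tests.

## Validation protocols

`bootstrap_plsda()` implements the repeated balanced 70/30 protocol: per
iteration a class-stratified random split, autoscaling fitted on the
training block only, the number of latent variables chosen by
leave-one-out cross-validation on the training block (ties toward fewer),
a PLS-DA fit, and accuracy/specificity/sensitivity on the held-out block;
aggregates are means and standard deviations of per-iteration metrics
over 150 iterations by default (iteration *i* uses `seed + i`). The name
"bootstrap" is kept for fidelity to the protocol's usual label, but the
resampling is subsampling without replacement. Optional in-fold
PCA-guided feature selection (`feature_select_fraction`) reproduces the
feature-selection variant of the pipeline; everything fitted from data
(scaling, selection, LV choice) is refit inside the training fold — the
leakage canary in the test suite demonstrates a label-copy feature scores
~100% while a shuffled copy scores ~50%.

`permutation_null()` re-runs the full protocol on shuffled labels
(default 20 protocol iterations per permutation — the null only needs
the aggregate — with the count an explicit argument) and reports
`p = (1 + #{null >= observed}) / (n_perm + 1)`. With `n_perm = 20` the
attainable resolution is 1/21 ≈ 0.048, just below 0.05, so type-I
calibration at the 5% level follows from exchangeability alone and is
independent of the per-permutation iteration count.

Two properties of this protocol matter when reading results. First, a
*single* finite null dataset has a dataset-conditional mean accuracy that
iteration count cannot pull to 50%: the latent-variable selection latches
onto the dataset's chance structure, and across independent null cohorts
of 20+20 samples x 200 channels the per-cohort means spread with sd ≈ 8
percentage points (mean 50). Calibration statements are therefore made as
averages over independent cohorts with the Monte-Carlo standard error
taken across cohorts. Second, with only a few informative channels among
hundreds of autoscaled ones, the first latent variable's achievable
accuracy is capped by noise-channel dilution regardless of per-channel
signal strength; the feature-selection variant removes that cap, which is
why the power analysis (fold-change 3 on five H3O+ channels, 20 animals
per class) is run on the H3O+ block with in-fold selection, where it
reaches ~96-99% mean accuracy.

Ages are analysed as independent strata (plus a pooled stratum), matching
the per-age layout of the study's accuracy tables; repeated measures per
animal across ages are not modelled by the classifiers, a caveat shared
with the original analyses.

## Phenotype statistics

`compare_groups()` dispatches on a declared design and distribution
attribute — normality is the caller's claim, not auto-tested: independent
+ normal → two-sample t-test (Welch by default; the pooled-variance
variant is an argument since the original software's default is
ambiguous); independent + free → Mann-Whitney U, exact for combined
n ≤ 20 without ties; repeated + normal → one-way repeated-measures ANOVA
with Bonferroni-adjusted pairwise paired t-tests; repeated + free →
Friedman with Bonferroni-adjusted pairwise Wilcoxon signed-rank tests.
All tests are two-sided. Sphericity correction for the repeated-measures
ANOVA is not applied by default. Degenerate post-hoc pairs
(zero-variance differences) report NA rather than a fabricated p-value,
and a Friedman test on fully tied data reports statistic 0. Diagnostic
flags are exact at their boundaries: hyperglycaemia strictly above
11.1 mmol/L, impaired glucose tolerance in [7.8, 11.1) — inclusive below,
open above, so exactly 11.1 carries neither flag — and the insulin
ceiling at 15 ng/mL.

## Numerical and design choices

* Sample standard deviation (n−1) everywhere a scale is estimated.
* PLS deflation stops early if the response block is exhausted; the
  latent-variable count actually extracted is reported.
* The LOO latent-variable search only compares counts reachable in every
  fold.
* Outlier flagging uses the conventional cutoff
  `k(n−1)/(n−k) · F_{1−alpha}(k, n−k)`: larger `alpha` flags more
  samples, `alpha → 0` flags none.
* All randomness flows from integer seeds through one derivation function
  (a Lehmer-style map kept inside 32-bit range), so every report is
  reproducible bit for bit; `run_study()` writes a manifest with MD5
  checksums of every output and is byte-identical on rerun.
* Problem sizes in the test suite and acceptance script (cohorts of
  20/class, 150-iteration protocols, 20-permutation nulls, 30-60
  replicate cohorts for calibration rates) were chosen to make the
  Monte-Carlo bands quoted above meaningful at desk scale.

## Known limitations

* The generator's clean log-normal model makes preprocessing invariances
  exact by construction; real data would stress baseline correction and
  peak deconvolution steps that are out of scope here (AMDIS-style
  deconvolution and library identification are deliberately not
  implemented; compound names ride along as labels).
* Pseudo-inverse LDA ignores zero-within-variance directions (see above).
* Single-linkage RT clustering can chain nearby compounds under large
  drift; align traces first when dense traces exist.
* The per-age classifiers treat acquisitions as independent; animal
  identity links samples across ages and a mixed-effects extension would
  be the principled refinement.
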