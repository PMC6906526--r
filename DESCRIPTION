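Package: murivoc
Title: Longitudinal Volatile Faecal Metabolome Discrimination for Mouse
    Models of Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating mouse genotypes and ages from
    volatile organic compound (VOC) profiles of faecal headspace.
    Implements SIFT-MS spectral preprocessing (precursor-ion
    normalization, hydrate/isotopologue humidity diagnostics,
    reserved-channel removal, multi-precursor concatenation), GC-MS
    preprocessing (internal-standard normalization, correlation
    optimised warping alignment, retention-time feature assembly),
    multivariate cores (PCA screening, canonical linear discriminant
    analysis, NIPALS partial least squares discriminant analysis),
    resampling validation (leave-one-out cross-validation, balanced
    70/30 split bootstrap with latent-variable selection, permutation
    null analysis), univariate phenotype statistics, and a synthetic
    cohort generator emulating a longitudinal study design
    (genotype x sex x age with bodyweight, blood glucose and plasma
    insulin trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
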