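Package: syndromix
Title: Syndromic Outcome Metrics for Multivariate Preclinical Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives composite "syndromic" outcome metrics from multivariate
    preclinical outcome batteries (behavioural, histological and general-health
    measures collected on the same subjects), with spinal cord injury models as
    the motivating application. Principal components are extracted from the
    pooled cross-correlation matrix (with multiple imputation for sparse
    missingness), retained by the consensus of the Kaiser, scree and factor
    over-determination rules, and named by salient loadings. Reliability and
    validity of the resulting metrics are tested by factor pattern-matching
    statistics (root-mean-square difference, coefficient of congruence,
    Pearson r, and the salient variable similarity index with a Monte-Carlo
    permutation null), variable-subset and case-subset cross-validation,
    equalized-n subsampling, sparse PCA via L1-penalized matrix decomposition,
    and injury-gradation ANOVA/ANCOVA on component scores. A seeded synthetic
    data generator with known latent structure provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
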