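Package: nparcluster
Title: Nonparametric Rank-Based Inference for Clustered Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Purely nonparametric estimation of and inference on relative
    (Wilcoxon-Mann-Whitney) effects in designs where each subject contributes
    a cluster of possibly correlated replicate observations, such as two
    hemispheres per patient or several teeth per subject.  Supports flexible
    weighting of clusters, groups and the reference distribution
    (pseudo-rank and classical rank schemes as special cases), consistent
    covariance estimation with a small-sample bias correction, Wald-type and
    ANOVA-type global tests, and single-step multiple contrast test
    procedures with multivariate t approximation, Satterthwaite-Welch
    degrees of freedom and range-preserving (Fisher-transformed)
    simultaneous confidence intervals.  Handles metric, ordinal and
    dichotomous outcomes through normalized empirical distribution
    functions (mid-ranks under ties).  Includes a simulation harness for
    type-I error and power studies under Gaussian-copula dependence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
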