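Package: clockrsa
Title: Representational Similarity Analysis of Learned Temporal Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyze how learning the temporal structure of event
    sequences reshapes multi-voxel fMRI pattern similarity. Implements
    pre/post pattern-similarity-change representational similarity analysis
    against competing time metrics (virtual clock time, sequence order, real
    elapsed time), two-level permutation inference (subject-level shuffles
    transformed to Z-scores, group-level sign-flip tests, permutation
    repeated-measures ANOVA), linear mixed-model comparisons with likelihood
    ratio tests, non-metric multidimensional scaling of model-derived
    representational distances, a volumetric searchlight engine with
    threshold-free cluster enhancement and small-volume correction, and the
    companion behavioral analyses (timeline construction, sorting, swap
    errors, generalization bias). A synthetic-data module generates designs,
    behavior, and multi-voxel patterns with planted statistical structure so
    the full pipeline is testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
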