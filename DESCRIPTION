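Package: gazealign
Title: Group-Level Comparison of Eye-Movement Scanpaths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical comparison of two groups of eye-movement scanpaths.
    Fixation sequences are assigned to landmark-derived areas of interest,
    temporally binned into symbol strings, and compared pairwise with the
    Needleman-Wunsch global alignment algorithm under a distance- and
    semantics-weighted substitution matrix (the ScanMatch scheme). The
    resulting similarity matrix is projected to two dimensions with t-SNE,
    group distributions are compared with a permutation Cramer
    (Baringhaus-Franz) test, and the temporal contribution is isolated by
    comparing classifiers trained with and without temporal information via
    the 5x2 cross-validated paired t-test, using character-permuted control
    scanpaths as the spatial-only reference. Includes a synthetic gaze
    generator with controllable null, spatial-only and temporal-only group
    differences, and a Levenshtein + non-metric multidimensional scaling
    benchmark pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    xgboost,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
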