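Package: repdyn
Title: Time-Resolved Decoding, Temporal Generalization, and Model-Based
    MEG-fMRI Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the representational dynamics of task context
    and object processing in epoched neural time series. Implements
    time-resolved pairwise maximum-margin decoding with supertrial averaging,
    temporal generalization (train x test time) analysis, within- and
    between-task-type cross-decoding, time-resolved representational
    similarity analysis (32-condition dissimilarity matrices), model-based
    MEG-fMRI fusion via squared Spearman correlation and commonality analysis,
    and the accompanying nonparametric inference: sign-permutation
    maximum-cluster-size tests in one and two dimensions, condition-relabelling
    randomization tests for fusion time courses, and bootstrap confidence
    intervals for peak latencies. A synthetic-data module generates the full
    factorial task x category design with known ground-truth signal structure
    so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    parallel,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
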