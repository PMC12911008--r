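Package: devfuse
Title: Multimodal Prediction of Motor and Executive-Function Development
    from Early-Childhood Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-wave longitudinal preschool cohorts with
    network-structured resting-state functional connectivity, MABC-2-like
    motor percentiles and executive-function scores; extracts connectivity
    vectors and twelve weighted graph-theory metrics with null-ensemble
    z-scores; computes reliability-weighted executive-function composites and
    median-split developmental outcomes; trains a four-channel multimodal
    fusion classifier (connectivity, graph, motor, cognitive channels) under
    a leakage-free stratified cross-validation protocol with fold-internal
    multiple imputation; and quantifies grouped permutation feature
    importance, growth-slope subgroups, partial correlations and
    spline-versus-linear mixed-model trajectory comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    lme4,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
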