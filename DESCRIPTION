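Package: trajmorbid
Title: Longitudinal Comorbidity Trajectory Analysis for Psychiatric Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds yearly cumulative-diagnosis state sequences from
    registry-style first-diagnosis event data, computes censoring-aware
    optimal-matching dissimilarities with set-overlap substitution costs
    and first-order Markov imputation of censored tails, reduces the
    dissimilarity matrix to principal dimensions by classical
    multidimensional scaling with out-of-sample projection, clusters the
    scores with Ward's method, and runs the epidemiological and
    association layers (cumulative incidence, relative risks,
    time-dependent Cox hazards for ordered diagnosis pairs, MANCOVA and
    multinomial-logit association tests). Includes a synthetic registry
    generator with planted latent trajectory classes so the full pipeline
    is testable without access to individual-level register data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    survival,
    nnet,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
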