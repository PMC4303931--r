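Package: psfmeta
Title: Hierarchical Bayesian Meta-Analysis of Plant-Soil Feedback Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysing pairwise plant-soil feedback experiments.
    Computes Hedges' d standardized mean differences with the sampling
    covariances induced by shared conspecific control soils, extracts
    patristic distances from a time-scaled phylogeny, and fits a hierarchical
    Bayes linear meta-regression of feedback effect size on phylogenetic
    distance that accounts for both sampling dependence (shared controls) and
    hierarchical dependence (experiments nested in studies). Includes subgroup
    models, species-trimming and distance-balanced resampling robustness
    checks, publication-bias diagnostics (funnel data, Duval-Tweedie trim and
    fill, cumulative meta-analysis ordered by precision), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
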