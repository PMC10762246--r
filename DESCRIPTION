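Package: socialdrift
Title: Timing of Social Information in Evidence-Accumulation Models of
    Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the timing of social information shapes
    perceptual confidence judgments. Implements a generative
    evidence-accumulation model in which an observed choice of another person
    enters the decision process both as an instantaneous shift and as a
    continuous drift, with an 11-category ordinal confidence likelihood built
    from symmetric criteria on the latent evidence axis. Provides balanced
    within-subject trial schedules for early/late social information designs,
    a synthetic-data generator (including pathological subjects for testing
    exclusion rules), Brier-based scoring and exclusion preprocessing,
    hierarchical Bayesian fitting of all eight shift/drift model variants with
    PSIS-LOO model comparison and parameter recovery, and ordered-probit
    signal-detection analyses of discrimination ability by social-information
    timing and validity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
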