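Package: transitr
Title: Transitive-Inference Task Design, Behavioural Modelling and
    Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transitive inference over one-dimensional
    reward hierarchies. Generates interleaved and progressive training
    schedules and in-scanner trial lists; simulates behavioural cohorts
    (binomial premise/inference responses, gamma latencies, missing
    responses) under retrieval-based (AND) and encoding-based (OR)
    generative regimes; fits both descriptive models by Monte-Carlo
    evaluation of a normalised retrieval-probability likelihood with
    inverse-transform sampling and cross-entropy minimisation; builds the
    accuracy and latency mixed-model designs; simulates voxel-level BOLD
    with haemodynamic convolution, autocorrelated noise and exponential
    repetition suppression; estimates single-discrimination betas by the
    least-squares-separate method; and implements the distance-effect
    representational similarity analysis with pseudoinverse pattern
    decomposition, nuisance predictors, mixed-model fitting and a
    sample-size-dependent residual-outlier rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
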