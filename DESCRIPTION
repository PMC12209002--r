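Package: capdyn
Title: Co-Activation Pattern Dynamics of Executive Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based co-activation pattern (CAP) analysis of parcel-level
    BOLD time series: frame selection, correlation-distance k-means clustering
    with consensus model-order selection, temporal state-graph metrics
    (occurrence, duration, resilience, IN-/OUT-degree, betweenness), grouped
    behavioral partial least squares correlation with permutation and bootstrap
    inference, and linear/mixed outcome models linking pre-surgical network
    dynamics to post-surgical attentional performance. Ships a hidden-Markov
    synthetic cohort generator with a planted brain-behavior latent axis so the
    full pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    lme4,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
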