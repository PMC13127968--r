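Package: rotadecode
Title: Time-Resolved EEG Decoding of Rotation-Tolerant Object Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-resolved multivariate
    decoding of object identity from epoched EEG under in-plane image
    rotation. Generates counterbalanced rapid serial visual presentation
    designs (5 Hz and 20 Hz), synthesizes multi-subject epoched data with
    rotation-specific and rotation-tolerant signal components, and analyses
    them with shrinkage linear discriminant analysis under fixed-rotation and
    rotation-tolerant cross-validation schemes, channel-searchlight
    topographies, cross-validated pairwise-decoding representational
    dissimilarity matrices with partial-correlation representational
    similarity analysis, temporal generalization within and across
    presentation rates, and group-level Bayes factors from notched (interval
    null) Cauchy priors with bootstrap confidence bands and latency
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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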