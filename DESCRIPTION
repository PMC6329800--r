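Package: featrpe
Title: Feature-Specific Reward Prediction Errors in Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how neurons encode feature-specific reward
    prediction errors (RPEs) during feature-based reversal learning. Implements
    a family of dimension-weighted reinforcement-learning models with
    maximum-likelihood fitting, cross-validation and AIC comparison; a
    simulator for the three-dimension (color, location, motion) deterministic
    reversal task and for event-locked Poisson spike trains with planted
    encoding structure; a sliding-window Spearman / partial-correlation
    classifier that labels neurons as carrying outcome, nonspecific-RPE or
    feature-specific-RPE signals; population latency, prevalence-bootstrap and
    color-tuning-index statistics; an attention-transfer contrast; and
    waveform-based cell-class analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
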