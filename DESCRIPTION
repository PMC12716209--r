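Package: senoscreen
Title: Image-Based Screening for Therapy-Induced Senescence with Lamin Reporters
Version: 0.1.0
Authors@R:
    person("Anna", "Verdier", email = "anna.verdier@example.org",
           role = c("aut", "cre"))
Description: Per-nucleus quantification of two-channel lamin reporter images and a
    regression-band classifier for therapy-induced senescence. Detects nuclei on the
    lamin A channel (Gaussian blur, Li minimum cross-entropy threshold,
    Laplacian-of-Gaussian seeding, seeded watershed), measures per-ROI mean
    intensities across arbitrary channels, fits the proliferating-control lamin B1 ~
    lamin A linear model with an R-squared heterogeneity correction, and flags cells
    with high lamin intensities or intensities deviating from the control prediction
    band. Includes mean + 2 SD marker-positivity scoring, confusion-matrix validation
    against ground truth, semi-log growth-rate and doubling-time fitting, and a
    synthetic-data generator (per-cell intensity tables and rendered multi-channel
    scenes with label masks) for end-to-end testing with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
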