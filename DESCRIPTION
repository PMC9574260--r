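Package: predlook
Title: Anticipatory-Looking Analysis for Two-Picture Preferential-Looking Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for webcam eye-tracking studies of
    linguistic prediction in two-picture preferential-looking displays.
    Provides experimental-design generation with counterbalanced sentence
    conditions, screen-proportional area-of-interest scaling, conditioning of
    raw irregular gaze samples into binned binary fixation series (gap-aware
    Gaussian smoothing, bounded linear interpolation onto a regular grid,
    half-open AOI coding, 100 ms binning, low-looking trial exclusion),
    growth-curve analysis of empirical fixation log-odds with orthogonal
    polynomial time terms, cluster-mass permutation tests against chance and
    between conditions, prediction-window binomial mixed models with
    chi-squared model comparison and BIC-approximate Bayes factors, and
    free-association stimulus-norming statistics.  A synthetic gaze generator
    with logistic target-fixation time-courses supports calibration and
    parameter-recovery testing when raw recordings are unavailable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
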