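Package: gmse
Title: Generalized Multiscale Entropy Analysis of Physiologic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the multiscale complexity of physiologic
    time series, with an emphasis on heart rate variability. Implements the
    generalized multiscale entropy family in which coarse-graining is
    performed with a selectable statistical moment (mean, variance, or
    skewness) of non-overlapping segments, sample entropy and quadratic
    sample entropy estimation with field-standard tolerance conventions, a
    scale-summed complexity index, a moving-window artifact filter for
    cardiac interbeat (RR) interval series, synthetic reference-signal
    generators (white noise, 1/f noise, periodic signals, AR(1), and
    RR-interval-like cohorts with labeled ectopy), and cohort-level batch
    analysis with nonparametric group comparison. A command-line interface
    exposes the full pipeline for shell use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
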