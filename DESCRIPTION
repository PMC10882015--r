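Package: heatrends
Title: Percentile-Based Heatwave Detection, Annual Indices, and
    Persistence-Aware Trend Analysis for Gridded Daily Temperatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heatwaves on gridded daily maximum and minimum 2-m
    temperature as runs of three or more days above reference-period
    percentile thresholds (95th, 97.5th, 99th), in day-only and joint
    day-night modes; reduces per-cell events to nine annual indices
    (affected area, maximum duration, peak and cumulative temperature,
    heatwave index, and their night-time counterparts); estimates decadal
    trends with Sen's slope and the modified Mann-Kendall test under the
    scaling hypothesis (long-term persistence via a maximum-likelihood
    Hurst exponent and a scaled arcsine variance with empirical bias
    correction); and overlays annual affected-area masks with gridded
    population counts to produce heat-exposure time series. Includes a
    synthetic-data generator (seasonal cycle, AR(1) or fractional Gaussian
    noise anomalies, secular trend, injectable events, clustered
    population rasters) so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
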