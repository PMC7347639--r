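Package: pollenproxy
Title: Validating Internet Search Volumes as a Proxy for Airborne Pollen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well regional internet search volumes
    approximate observed early-season airborne pollen concentrations. Provides a
    synthetic generator of coupled pollen/search daily panels (bimodal pollen
    seasonality, lagged monotone search response, 0-100 rescaling with
    zero-censoring of low volumes, replicate download noise, station-style
    missingness), CSV readers and station-to-market-region matching, station-year
    data-quality metrics and inclusion rules, a transform stack (windowing,
    max-normalisation, log transform, tricube local-linear LOWESS smoothing),
    per-site-year Spearman rank correlation with quartile stratification by data
    missingness and peak signal-to-noise, pollen season onset estimation under
    cumulative-fraction, consecutive-day and absolute-threshold definitions, and
    an end-to-end configurable pipeline with text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
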