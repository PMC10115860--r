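Package: stormlag
Title: Matched Distributed-Lag Models for Tropical Cyclone Hospitalization Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating short-term hospitalization risk associated
    with tropical cyclone exposure in small areas (ZIP code tabulation areas).
    Implements ZCTA-level wind exposure classification and summaries, a matched
    exposed/unexposed-day design (ten control days drawn from other years
    within a seven-day day-of-year window, excluding days near other storms), a
    distributed-lag mixed-effects Poisson model over lags -2..7 with ZCTA
    random intercepts and beneficiary offsets, lag-specific and cumulative
    relative risks with delta-method confidence intervals, stratified
    effect-modification analyses by individual and community characteristics,
    community covariate processing (areal interpolation, time-weighted
    averaging, median splits, stability checks), and a fully parameterised
    synthetic-data generator for design calibration and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
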