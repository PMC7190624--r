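Package: snowtrack
Title: Snowmelt Tracking and Step-Selection Analysis of Arctic Spring Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse spring migration of Arctic-breeding raptors in
    relation to the northward progression of snowmelt. Provides a simulator of
    dynamic snow-cover, temperature, NDVI and wind raster series together with
    agents whose step choices follow a known conditional-logit rule; readers
    and quality filters for Movebank-style Argos/GPS tracks; fixed-interval
    burst resampling and step geometry; first-passage-time segmentation of
    spring migration; daily raster annotation, day-length, wind support and
    crosswind, and past-to-future environmental lag tables; step-selection
    strata construction with exponential distance sampling of alternatives;
    an exact conditional logistic regression fitter with cluster-robust
    standard errors; mixed-model lag regressions; AIC model comparison with
    Akaike weights; and used-habitat-calibration (UHC) model validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    geosphere
Config/testthat/edition: 3
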