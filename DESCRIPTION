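Package: metalrisk
Title: Heavy-Metal Dietary Risk Indexes, Risk-Level Classification and
    Multi-Step Early-Warning Forecasts for Food Surveillance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for turning daily heavy-metal detection records from food
    surveillance sampling into quantitative dietary risk assessments and
    forward-looking risk warnings.  Computes per-day, per-metal Nemerow
    integrated pollution indexes (NIPI), target cancer risk (TCR) and target
    hazard quotients (THQ) from detection tables with below-detection-limit
    censoring; fuses the nine per-metal indexes into comprehensive daily
    indexes with entropy weights; classifies days into data-driven risk
    levels with K-means++ clustering and silhouette-based selection of the
    number of levels; and forecasts future risk levels with a voting
    ensemble of recurrent one-step predictors (simple recurrent, GRU and
    LSTM cells) applied recursively for multi-step horizons.  A seeded
    synthetic-data generator reproduces the statistical structure of
    surveillance detection data so the whole pipeline can be exercised
    without access-restricted national datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster
Config/testthat/edition: 3
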