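Package: nephqc
Title: Humidity and Gravimetric-Equivalency Quality Control for Passive
    Nephelometer PM Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control of passive nephelometer particulate-matter
    measurements collected during solid-biomass cookstove use. Implements
    relative-humidity correction-factor models (empirical quadratic-ratio and
    log-linear forms, with or without the conventional 60% RH threshold),
    gravimetric-equivalency conversion regressions (through-origin linear,
    log-log, log-log with a hinge-spline knot selected by cross-validated grid
    search, and log-log quadratic), one-step combined humidity plus gravimetric
    adjustment models, leave-one-out cross-validated model comparison across 21
    adjustment approaches, instrument-log ingestion and filter-sample
    processing, and a synthetic co-location campaign generator for testing the
    full pipeline without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
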