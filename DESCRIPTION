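Package: phenorisk
Title: Phenology-Informed Population Viability Analysis for Monitoring Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Month-stratified population viability analysis for long-term
    monitoring surveys of fishes and zooplankton. Screens catch-per-unit-effort
    time series, fits a station-replicated random walk with drift by maximum
    likelihood (shared drift and equal process variance within a region),
    attaches parametric-bootstrap confidence intervals, and converts the fitted
    drift and process variance into quasi-extinction (critical decline) risk
    via the inverse-Gaussian first-passage probability for Brownian motion with
    drift, under baseline, best-case and worst-case scenarios. Detects
    high-abundance phenology windows (months holding at least 80% of mean
    annual catch), builds monthly risk profiles, pairs fish predators with
    co-occurring zooplankton prey inside those windows, and projects
    predator-prey risk divergence over a decade. Includes a synthetic
    survey-data generator so the whole pipeline is testable without agency
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
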