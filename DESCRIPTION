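Package: phenocast
Title: Automated Species-Level Plant Phenology Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for automated, species-level forecasting of plant
    phenology (budburst, flowering, fruiting, fall colors). Fits
    process-based thermal-forcing phenology models to status-based
    monitoring observations, combines them into a cross-validated stacked
    ensemble, downscales coarse sub-daily climate forecasts to a fine grid
    with per-cell monthly asynchronous regression, runs gridded
    multi-member forecasts of event dates with uncertainty and anomaly
    maps, and verifies forecasts against subsequently observed events.
    Includes seeded synthetic-data generators so the full pipeline is
    testable offline, JSON model storage, and netCDF grid input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DEoptim,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ncdf4,
    purrr,
    quadprog,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
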