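Package: flywayr
Title: Probabilistic Flyway Mapping from Bird Telemetry with Dynamic
    Brownian Bridge Movement Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates utilization distributions (UDs) for full migration
    events from satellite and GPS telemetry using dynamic Brownian bridge
    movement models with sliding-window, BIC-based Brownian motion variance
    estimation; aggregates event UDs into individual, population, species
    and multi-species flyway maps by migration-duration weighting; extracts
    50/75/99 percent cumulative probability contours classifying stopover
    sites, core movement areas and flight corridors; and runs a subsampling
    sensitivity analysis based on the percent volume of intersection between
    subsampled and full flyway UDs. Includes preprocessing for Argos
    location-class error assignment, hourly best-fix retention and speed
    plausibility filtering, plus a synthetic migratory-track simulator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
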