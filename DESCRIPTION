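Package: cropcarbon
Title: County-Level Downscaling of Crop-Farming Carbon Emission Intensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An activity-based greenhouse-gas inventory and random-forest
    downscaling pipeline for crop-farming carbon emissions. Computes regional
    CO2-equivalent emissions from activity data and emission factors,
    normalizes them to intensity per unit land area, screens candidate
    socio-economic indicators by random-forest relative importance, fits a
    downscaling model that transfers provincial intensity to counties via
    per-area proxy covariates, enforces a provincial mass-balance constraint
    on the county estimates, and validates results against reference
    county-level products. Ships a seeded synthetic-data generator with a
    known province-to-county generative link so every stage can be exercised
    and tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
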