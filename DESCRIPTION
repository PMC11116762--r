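Package: vegsens
Title: Sensitivity of Vegetation Productivity to Rising CO2
Version: 0.1.0
Authors@R:
    person("Yuan", "Developer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the sensitivity of terrestrial gross primary
    production (GPP) to rising atmospheric CO2 (beta), expressed as the
    relative increase in GPP per 100 ppm of CO2, from gridded annual climate
    fields. Implements vapor pressure deficit (VPD) derivation from
    temperature, humidity and altitude; per-pixel 15-year moving-window
    multiple regression of GPP on CO2, VPD and maximum temperature; linear
    trend mapping with significance masks and area-fraction summaries; and
    attribution of beta changes to VPD, water availability and nutrient
    availability via standardized regression coefficients and partial
    correlations. Includes a seeded synthetic-scenario generator with known
    ground truth for parameter-recovery testing, plain-text gridded I/O, and
    an end-to-end pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
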