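Package: ancrain
Title: Precipitation-Attributable Disruption of Antenatal Care Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how precipitation disrupts routine health-service
    delivery from facility-month service-count panels and gridded daily rainfall.
    Computes ETCCDI-informed monthly precipitation indices (monthly cumulative
    totals and Rx5day with lagged, squared, cubed and interaction expansions),
    assigns facilities to grid cells by nearest-neighbour search, assembles
    log-linear panel design matrices with standard cleaning rules (sparse-
    facility exclusion, confirmed-closure zeros, altitude imputation,
    collinearity screening), fits paired with/without-precipitation OLS models
    with backward stepwise AIC selection and likelihood-ratio comparison, and
    derives the counterfactual-difference disruption statistic, deficit-filtered
    aggregates, extreme-event shares and affected-pregnancy conversions.
    Includes scenario machinery for substituted precipitation series
    (early-period counterfactuals and projection ensembles with
    lowest/mean/highest member selection) and a synthetic-data generator that
    emulates DHIS2-style reporting panels and reanalysis-style rainfall grids
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
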