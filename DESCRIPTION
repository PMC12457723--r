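Package: ascoalloc
Title: Reproductive Allocation, Shoot Demography and Phenology of Ascophyllum nodosum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying reproductive allocation and phenology of the
    intertidal macroalga Ascophyllum nodosum from shoot-segment field records.
    Implements annual vegetative growth, biomass turnover, reproductive effort
    and annual reproductive allocation (annRA) at shoot and site level, carbon
    conversion and areal carbon-flux upscaling, negative-binomial count-age
    models of receptacle formation along the primary axis, the 15th-of-month
    Julian-day phenology convention with autumn wrap, and latitudinal
    meta-regressions across the species distribution range. Includes a
    calibrated synthetic shoot-population generator with site profiles spanning
    the observed turnover and reproductive-effort ranges, CSV readers/writers
    for the shoot, segment, receptacle-pool, site and meta-record schemas, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    glmmTMB,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
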