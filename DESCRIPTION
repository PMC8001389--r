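Package: eggtherm
Title: Thermal Biology of Insect Egg Development and Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for egg-cohort thermal biology experiments in
    insects: Kaplan-Meier survival estimation and log-rank comparison of egg
    cohorts across temperature and relative-humidity conditions, Poisson
    regression of development time, linear development-rate modelling to
    estimate the lower development threshold (T0) and thermal constant (K),
    degree-day accumulation and hatch-date forecasting over daily temperature
    series, and back-calculation of the field oviposition window from staged
    egg and larva records. Includes a calibrated synthetic-data generator for
    laboratory cohorts, seasonal temperature series and field stage records,
    so the full pipeline can be exercised and validated without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
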