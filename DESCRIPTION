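Package: pigqsc
Title: Quick Scan Handling and Hygiene Calculator for Weaned-Piglet Farms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multi-criteria evaluation of post-weaning piglet management.
    Scores farms on ten handling and hygiene indices (pre-weaning handling,
    batch management, biosecurity, water and feed management, health program,
    stockmen training, and per-room temperature, ventilation and floor/density
    indices), each 0-10 from weighted checklist factors, summing to a 0-100
    farm score. Includes benchmarking analytics (descriptive statistics with
    SPSS-compatible percentiles, Pearson correlation tables with significance
    stars, quartile group comparisons with one-way ANOVA and
    Student-Newman-Keuls letters) and a calibrated synthetic farm-cohort
    generator for end-to-end testing without confidential farm data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
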