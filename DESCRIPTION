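Package: pon1qsar
Title: QSAR Models for Paraoxonase-1 Q/R Isozyme Hydrolysis Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates quantitative structure-activity relationship
    (QSAR) models for the relative hydrolysis rates of substrates of the human
    serum paraoxonase-1 (PON1) Q192 and R192 isozymes. Ships a curated
    30-compound substrate table (lactones, thiolactones, aryl esters and
    organophosphates with rates relative to phenyl acetate = 100), computes the
    3D molecular descriptors used by the published four-variable models
    (mass-weighted 3D-MoRSE signals, the van-der-Waals-volume-weighted WHIM
    accessibility index E1v, the mass-weighted GETAWAY H autocorrelation, and
    the order-0 structural information content), performs genetic-algorithm
    multiple-linear-regression (GA-MLR) descriptor selection, computes fitting,
    leave-one-out/leave-many-out cross-validation and external validation
    statistics with y-scrambling, and characterizes each model's applicability
    domain with leverage-based Williams plots. A synthetic-data generator with
    planted sparse linear signals makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
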