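Package: polystress
Title: Multi-Level Analysis of Translational and Proteomic Stress Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing gene regulation during environmental stress
    at three levels: translation profiles from four-pool polysome
    fractionation (profile percentages, sum-of-differences and weighted-score
    translation-ratio statistics, cutoff-plus-curation calling), spectrum-count
    proteome time courses (detection filtering, least-squares sample
    calibration, log2 trajectories, quadratic-linear regression with temporal
    profile classification), and cross-level integration (mRNA direction
    calls, concordance and discordance classification, correlations,
    hypergeometric gene-set enrichment, Spearman-distance average-linkage
    clustering). A seeded synthetic-data generator with planted effects makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
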