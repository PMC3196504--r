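Package: comdemog
Title: Comparative Demographic Inference for Codistributed Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether codistributed species share a common
    demographic history, built around the Joshua tree / yucca moth study design.
    Simulates coalescent genealogies under piecewise-constant and exponential
    growth histories, evolves sequences under HKY, TrN and K81 substitution
    models with discrete-gamma rate heterogeneity, computes expansion
    diagnostics (Fu's Fs from the Ewens sampling distribution, Tajima's D,
    mismatch-distribution tau dating), fits a single-genealogy exponential
    growth coalescent likelihood, runs hierarchical AMOVA, Mantel
    isolation-by-distance and McDonald-Kreitman tests, and evaluates species
    distribution model surfaces (thresholds, Cohen's kappa, AUC, range-cell
    counts and non-analogue climate masks). Includes a synthetic community
    generator emulating the study's sampling design and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    generics,
    Biostrings,
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    broom,
    knitr,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
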