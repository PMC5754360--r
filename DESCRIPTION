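Package: sporememory
Title: Kinetic Modeling and Simulation of Phenotypic Spore Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the timing of Bacillus subtilis
    sporulation is imprinted on spore revival capacity through dilution of a
    revival-limiting enzyme ("phenotypic memory"). Implements a deterministic
    kinetic model of the sporulation cascade with closed-form and numerical
    solutions for spore yield, mean carried-over enzyme level and the
    enzyme-level distribution; a continuous-time stochastic branching-process
    simulator of single-cell life histories that serves as an independent
    Monte-Carlo check of the deterministic model; a synthetic time-lapse
    microscopy data generator emulating per-spore observation tables
    (heterochronic sporulation waves, fluorescent reporters, germination and
    outgrowth outcomes, frame-rate censoring); and the quantification layer
    used to analyse such tables (early/late classification, revival,
    germination and outgrowth frequencies, germination kinetics, yield and
    quality with wild-type normalization, Welch t tests, and
    quantity-vs-quality tradeoff sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
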