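Package: crosskit
Title: Genomic Cross-Performance Prediction and Breeding-Programme Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the mean genotypic value of candidate F1 crosses from
    genome-wide marker data. Fits an additive plus directional-dominance mixed
    model by REML, back-solves per-marker additive and dominance effects, and
    scores every parental combination with a closed-form progeny-mean equation,
    optionally combining traits through a linear selection index and filtering
    by plant sex. Includes a forward-in-time clonal breeding-programme
    simulator (multi-stage yield-trial pipeline, configurable dominance
    architecture) for comparing cross-performance selection against classical
    genomic estimated breeding values, plus deterministic fixture generators
    for genotype (VCF/HapMap) and phenotype files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
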