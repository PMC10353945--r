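Package: lofburden
Title: Rare Loss-of-Function Burden and Gene-Level Case-Control Odds Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-level rare-variant burden analysis under extreme
    case-control imbalance. Classifies annotated variants into stringent
    loss-of-function (S-LoF) and stringent synonymous (S-SYN) classes using
    genotype quality control, allele-frequency, annotation-confidence,
    brain exon-expression (pext) and protein-truncation filters; estimates
    per-gene case-control odds ratios with a sub-sampling procedure that
    matches the undiagnosed group size to the diagnosed group, attaching
    bootstrap empirical P values with confidence intervals; computes cohort
    burden statistics (carrier proportions, Fisher and Mann-Whitney
    contrasts, odds-ratio/expression correlations, coexpression-module
    summaries); and fits multivariable regression models of rare-variant
    carrier status and polygenic score against diagnosis, cognitive,
    socioeconomic and participation outcomes. A seeded synthetic-cohort
    generator emulates the data structure the analysis assumes so that
    every stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
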