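Package: bcrclonality
Title: B-Cell Receptor Repertoire Clonality and Longitudinal Turnover Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing UMI-corrected B-cell receptor (BcR) heavy-chain
    repertoires from paired tissue and blood samples collected before and after
    treatment. Aggregates AIRR-style sequence records into clonotypes, calls
    dominant (highly expanded) clones at a configurable frequency threshold and
    summarises their cumulative frequency ("impact"), quantifies clone sharing
    between compartments and longitudinal dominant-clone turnover, groups related
    clones by CDR3 amino-acid Hamming distance with a data-driven threshold,
    profiles repertoire diversity (Simpson, Shannon, Gini), mutation load and
    V/J gene usage, and joins repertoire summaries to clinical outcomes for
    nonparametric association testing. Includes a seeded synthetic-cohort
    generator with a ground-truth ledger so every pipeline stage can be tested
    against planted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
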