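Package: kpburden
Title: Rare-Variant Burden Analysis of Tryptophan and Kynurenine Pathway Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Candidate-gene rare-variant analysis for case-control cohorts:
    qualifying-variant filtering by protein-altering consequence and control
    population minor allele frequency, novel-variant detection with
    sequencing quality control (depth, allele balance, genotype quality),
    consensus in-silico pathogenicity scoring across dbNSFP-style prediction
    tools with REVEL and BayesDel calls, and per-gene case/control burden
    testing with exact conditional 2x2 tests (central, minimum-likelihood
    and Blaker two-sided methods) under Bonferroni correction. Ships a
    synthetic cohort generator with planted ground truth so the full
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    dplyr,
    GenomeInfoDb,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    SummarizedExperiment,
    tibble,
    tidyr,
    tools,
    utils,
    VariantAnnotation,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
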