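Package: genophen
Title: Genotype-Phenotype Correlation for Marfan-Spectrum Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genotype-phenotype correlation
    analysis of targeted gene-panel sequencing in the Marfan syndrome
    spectrum. Merges per-sample VCFs into a coverage-aware genotype matrix
    with quality-control filters, classifies variants by frequency and
    clinical class, reduces binary clinical signs by factor analysis of
    mixed data (FAMD) and predicts pathogenic-variant carriage from the
    first dimension, tests common variants by covariate-adjusted logistic
    regression with max-T permutation correction and builds sign-specific
    polygenic risk scores, tests rare variants by negative-binomial burden
    regression and gene-level SKAT-O, and compares joint rare-plus-common
    path models against an FBN1-only model by explained variance. A fully
    synthetic cohort generator with planted effects makes every stage
    testable without access to patient data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
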