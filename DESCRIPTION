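Package: pleioscan
Title: Cross-Phenotype Pleiotropy Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing shared genetic aetiology between two complex
    traits from genome-wide association study (GWAS) summary statistics:
    allele harmonisation of summary-statistics tables, LD score regression
    estimates of SNP heritability and cross-trait genetic correlation with
    sample-overlap intercepts, p-value-informed LD pruning with
    permutation-calibrated signal-overlap tests, regional Bayesian
    colocalisation under five hypotheses using approximate Bayes factors,
    cross-phenotype association statistics (S_hom/S_het) for correlated
    studies, inverse-variance-weighted replication meta-analysis with a
    direction-of-effect sign test, and a block-LD synthetic summary-statistics
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
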