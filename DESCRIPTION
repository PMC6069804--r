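Package: mrmetab
Title: Mendelian Randomisation of Clustered Metabolite Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pleiotropy-robust Mendelian randomisation of a single exposure
    (log body mass index) on many correlated outcomes (log metabolite
    concentrations) from individual-level data: genotype quality control and
    instrument selection (call rate, minor allele frequency, Hardy-Weinberg,
    association p-value, LD pruning), ratio / inverse-variance-weighted /
    Egger-regression / weighted-median causal-effect estimators with an
    individual-level bootstrap, L1-penalised counting of invalid instruments,
    Ward clustering of outcomes on the sqrt(1-R^2) correlation distance, and
    hypergeometric cluster enrichment of significant causal effects. Includes
    a synthetic-cohort generator with known ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
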