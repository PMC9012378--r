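Package: wprskit
Title: Weighted Polygenic Risk Scores with Tertile Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of weighted polygenic risk scores
    (wPRS) for case-control cohorts: PLINK bed/bim/fam and VCF genotype
    input, effect-allele harmonization, variant quality control (call rate,
    minor allele frequency, Hardy-Weinberg exact test, LD pruning), genotype
    principal components, additive ln(odds-ratio)-weighted scoring with mean
    imputation, pooled tertile risk stratification with unadjusted and
    covariate-adjusted logistic odds ratios (including a Firth-type
    penalized refit under separation), and nonparametric ROC evaluation
    (tie-corrected AUROC with DeLong confidence intervals, threshold
    sensitivity, specificity and accuracy, and an ordinal-table AUROC).
    Includes a synthetic cohort simulator for two case cohorts sharing one
    control group, used for end-to-end testing and parameter-recovery
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
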