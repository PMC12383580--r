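Package: cardioGRS
Title: Unweighted Genetic Risk Scores for Cardiometabolic Case-Control Cohorts
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analysis of unweighted additive genetic
    risk scores (GRS) built from small curated SNP panels. Provides a
    SummarizedExperiment-based cohort container with questionnaire-derived
    phenotypes, cohort assembly with explicit exclusion bookkeeping, BMI
    derivation and Tukey outer-fence outlier filtering, rule-based type 2
    diabetes and cardiovascular disease classification from self-reported
    history and medication classes, per-SNP Hardy-Weinberg equilibrium tests,
    GRS computation with 0-100 rescaling and tertile stratification, 2x2
    contingency-table statistics (cross-product odds ratios with Woolf
    confidence intervals, Pearson chi-square, Fisher exact, Mann-Whitney),
    and single-predictor ROC AUC estimation with stratified 10-fold
    cross-validation, percentile bootstrap confidence intervals and
    class-imbalance correction (downsampling or Gaussian age-matched
    resampling). A seeded synthetic cohort generator reproduces the
    statistical structure such studies assume, so every pipeline stage is
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
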