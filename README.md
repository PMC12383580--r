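# cardioGRS

Case-control analysis of **unweighted additive genetic risk scores** (GRS)
built from small curated SNP panels — the design used in nutrigenetics and
cardiometabolic-risk studies where a questionnaire-phenotyped cohort is
genotyped on a targeted panel (here, 18 SNPs in metabolic-pathway genes) and
asked whether carrying more risk alleles raises the odds of overweight or
obesity, type 2 diabetes (T2DM) or cardiovascular traits (CVD).

For a K-SNP panel, each sample's raw score is the number of risk alleles it
carries, `raw = Σ g_k ∈ [0, 2K]`, rescaled to `100·raw/(2K) ∈ [0, 100]` and
cut into exact thirds (low ≤ 100/3 < intermediate < 200/3 ≤ high), with
intermediate and high merged into one analysis group. Association is the
cross-product odds ratio `OR = ad/bc` of the group-by-outcome 2×2 table with
the Woolf log-method 95% CI, p from the uncorrected Pearson χ²;
discrimination is single-predictor logistic AUC with stratified 10-fold
cross-validation, percentile bootstrap CIs, and class-imbalance correction
by downsampling or Gaussian age-matched resampling. A seeded synthetic
cohort generator reproduces the statistical structure of such studies
(HWE genotypes, skewed BMI with age confounding, configurable stratum-level
outcome effects), so every stage is testable without access to restricted
data.

The package is Bioconductor-style: cohorts are `GrsCohort` objects extending
`SummarizedExperiment` (dosage assay, panel in `rowData`, phenotypes in
`colData`), with S4 accessors throughout.

## Worked example

```r
library(cardioGRS)

# a synthetic study-sized cohort: 4279 samples, 18-SNP panel
es  <- emulateStudy(seed = 1)
coh <- scoreCohort(es$cohort)          # adds grs_raw/grs_scaled/stratum
coh
#> GrsCohort: 4279 samples x 18 panel SNPs
#>   derived columns: bmi, t2dm, cvd, grs_raw, stratum

cd <- SummarizedExperiment::colData(coh)
median(cd$grs_scaled)                  # 41.67  (raw 15 of 36)
pct1(sum(cd$cvd), ncol(coh))           # 23.8   (% CVD-positive)

# association of the merged intermediate/high group vs low, per outcome
forestData(coh)[, c("outcome", "or", "ci_low", "ci_high", "p_value")]
#>            outcome   or ci_low ci_high  p_value
#> 1 overweight_obese 0.93   0.77    1.12  0.45
#> 2             t2dm 1.97   1.23    3.14  0.0038
#> 3              cvd 1.34   1.10    1.65  0.0044

# published group counts as direct input: 914/2746 vs 109/510 CVD+/CVD-
oddsRatio(contingency2x2(914, 2746, 109, 510))$or   # 1.557 -> prints 1.56
chiSquareTest(contingency2x2(914, 2746, 109, 510))$p_value  # 7.1e-05

# discrimination for CVD on a downsampled balanced set
aucReport(coh, "cvd", predictors = c("grs", "age", "bmi"),
          nBoot = 200, seed = 1)[, c("predictor", "auc", "ci_low", "ci_high")]
#>   predictor   auc ci_low ci_high
#> 1       grs 0.523  0.497   0.542
#> 2       age 0.716  0.697   0.734
#> 3       bmi 0.702  0.682   0.720
```

The single-seed odds ratios fluctuate around the configured stratum OR of
1.56 (the generator's marginal group OR is additionally attenuated by the
age/BMI terms — see the methods vignette); the AUC ordering
age > BMI > GRS, with a modest GRS AUC just above 0.5, is the expected
signature of an unweighted 18-SNP score against strong demographic
predictors.

A thin CLI over the same functions ships in
`inst/scripts/grs_pipeline.R` (subcommands `simulate`, `score`,
`associate`, `discriminate`, `all`), and `runPipeline()` writes the full
machine-readable bundle (`cohort_flow.json`, `table2.tsv`, `forest_or.tsv`,
`auc_report.tsv`, `hwe.tsv`, config echo and log).

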