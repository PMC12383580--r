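---
title: "Methods: unweighted GRS case-control analysis and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unweighted GRS case-control analysis and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioGRS)
```

## The model

cardioGRS analyses the association between an **unweighted additive genetic
risk score** and binary cardiometabolic outcomes in a case-control cohort.
For a panel of $K$ biallelic SNPs with configured risk alleles, a sample
carrying dosage $g_k \in \{0,1,2\}$ risk alleles at SNP $k$ receives the raw
score

$$\mathrm{GRS}_{\mathrm{raw}} = \sum_{k=1}^{K} g_k \in [0,\, 2K],$$

rescaled for interpretability to $100 \cdot \mathrm{GRS}_{\mathrm{raw}} /
(2K) \in [0, 100]$ and reported to two decimals. Every allele counts
equally: no GWAS effect-size weights are used, which keeps the score
transparent and robust to effect-size misestimation in small panels, at the
cost of some discriminative efficiency.

The scale is cut into exact thirds: *low* $\le 100/3$, *high* $\ge 200/3$,
*intermediate* in between. On an 18-SNP panel the attainable boundary scores
are 33.33 (raw 12) and 66.67 (raw 24); published cutoff notation of the form
"$\le 33.3$ / $\ge 66.7$" excludes both attainable boundary values while the
accompanying group summaries show 33.33 inside the low group. We therefore
fix the cutoffs as the exact thirds with *low inclusive of* $100/3$ and
*high inclusive of* $200/3$ — in raw-allele space for $K=18$: low $\le 12$,
intermediate 13–23, high $\ge 24$. This is the only reading that makes a
low-group median of 33.33 possible. Because high-GRS individuals are rare
under realistic allele frequencies, the intermediate and high strata are
merged into one analysis group, giving the 2-level exposure used everywhere
downstream.

Association is measured by the cross-product odds ratio of the
exposure-by-outcome 2×2 table with the Woolf (log-method) interval

$$\exp\!\left(\ln \widehat{OR} \pm z_{0.975}\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\right),$$

which is algebraically identical to the Wald interval of a single
binary-predictor logistic model (a property the test suite asserts to
$10^{-6}$). Zero cells receive the Haldane–Anscombe 0.5 correction, flagged
in the output; a cross pattern of two zero cells leaves the OR undefined and
is an error. p-values come from the **uncorrected** Pearson $\chi^2$: with
the large cell counts typical of these cohorts the continuity correction is
needless and would break agreement with published cross-products; it remains
available by flag. Fisher's exact test replaces $\chi^2$ in the descriptive
table whenever any expected cell is below 5.

## Phenotyping rules

BMI is weight/height² with the standard categories (normal < 25, overweight
25–29.9, obese ≥ 30 kg/m²; the binary analysis merges overweight and obese).
Extreme BMI values are removed **once**, before any statistics, by Tukey's
outer fences $[Q_1 - 3\,\mathrm{IQR},\; Q_3 + 3\,\mathrm{IQR}]$ computed on
the full matched cohort. Quartiles use Tukey hinges (median-of-halves, as
boxplots draw them) because the fence rule originates in boxplot practice;
the convention is configurable and recorded in the filter's output. There is
no iterative re-fencing.

Outcome statuses are rule-based from self-report. T2DM is positive on a
diabetes history flag or use of insulin, metformin or a sulfonylurea;
medication-only evidence is overridden to negative when the record also
carries a GLP-1 agonist or weight-loss prescription, since such prescribing
increasingly targets weight management in people without diabetes. Where a
record has *both* a positive history and the override medication, history
wins — the override exists to exclude weight-loss users, not to veto a
reported diagnosis. CVD is positive on any of hypertension, coronary artery
disease, stroke or dyslipidemia, or any antihypertensive, lipid-lowering or
antiplatelet/anticoagulant medication. The medication lexicon is a shipped,
editable TSV; unknown labels classify as `other` with a warning rather than
an error, because questionnaire vocabularies are open-ended.

**Risk alleles are configuration.** Panels in the field are published as
rsID + gene lists; the counted allele is part of the assay design. The
shipped default panel carries risk alleles curated from the external GWAS
literature and is labelled as such; all tests run on explicit synthetic
panels so that no scientific claim rests on the shipped orientation.

## Discrimination analysis

Each predictor is assessed alone: a one-variable logistic fit, scored by the
area under the ROC curve, computed by the rank (midrank-ties) method on the
model's linear predictor. For a monotone score this equals the
Mann–Whitney concordance of the predictor itself whenever the fitted slope
is non-negative — an identity the tests assert to $10^{-9}$ against a
pair-enumeration oracle. We deliberately rank the linear predictor rather
than the fitted probability: the two orderings are identical, but fitted
probabilities saturate to exactly 1.0 in double precision under strong
separation, manufacturing spurious ties. A constant predictor returns AUC
0.5 by the tie convention.

The point estimate is the mean out-of-fold AUC over **stratified** 10-fold
cross-validation (stratification keeps both classes in every fold; folds are
dealt round-robin within class after a seeded shuffle). The 95% CI is the
2.5/97.5 percentile of 1000 bootstrap replicates, each of which resamples
the balanced data with replacement *within outcome class* and recomputes the
whole CV-mean AUC. "Cross-validation before bootstrapping" admits two
readings; we bootstrap the data and recompute the CV estimate inside each
replicate (the bias-aware reading), and expose bootstrapping of the per-fold
AUCs as a cheaper `bootMode = "fold_auc"` alternative. Within-class
resampling preserves the balance that motivated the design and cannot
produce a single-class replicate.

Class imbalance is corrected before AUC estimation. For T2DM and CVD the
majority class is randomly downsampled to the minority size. For the
overweight/obese outcome the imbalance is chiefly an *age* imbalance, so the
majority class is instead resampled to the **Gaussian fit of the reference
class's age distribution**: weights proportional to
$\phi(x;\hat\mu_{\mathrm{ref}},\hat\sigma_{\mathrm{ref}})/\hat f_{\mathrm{tgt}}(x)$
(a kernel-density estimate of the target's own age density), sampled without
replacement down to the reference size. The resampled class's age mean and
SD are checked against the reference fit (10% tolerance); insufficient
support overlap produces a warning reporting the achieved moments rather
than silent failure. Bin-free importance reweighting was chosen over
histogram matching because it has no bandwidth-by-bin interaction and
degrades gracefully.

## The synthetic cohort generator

No public data accompany studies of this kind, so the generator is the
test-bed: it realises the statistical structure the analysis assumes, with
every parameter explicit in `cohortSpec()`.

* **Genotypes** are independent Binomial(2, $f_k$) draws — unlinked loci in
  HWE. Default frequencies spread 0.25–0.60 so the raw-score median sits
  near 15/36 (scaled 41.67) and roughly 16% of samples fall in the low
  stratum, matching the reference descriptives. LD and population structure
  are deliberately out of scope.
* **Age** is normal (mean 41, SD 8.6, truncated 18–80), giving median ≈ 41
  and IQR ≈ 11.6.
* **BMI** is linear in age (0.15 kg/m² per year) and raw GRS (0.05 kg/m²
  per allele) plus signed-lognormal noise
  $s\,\lambda(e^{|s|Z} - e^{s^2/2})$. The skew parameter is signed because
  the reference descriptives — median 29.09 with 29.5% of mass below 25 —
  are only attainable with a long *lower* tail (left skew), and indeed the
  source description calls its BMI distribution left-skewed even though
  questionnaire BMI is conventionally right-skewed. Defaults
  ($s = -1.2$, $\lambda = 4.5$, intercept 24.5) were calibrated once to the
  published median and overweight/obese fraction; the printed median/IQR
  pair and the 70.5% overweight fraction are mutually inconsistent under
  any unimodal shape, so the median and the fraction were prioritised and
  the realised IQR (≈ 8) is documented rather than forced.
* **Outcomes** are Bernoulli with logit = intercept + stratum effect
  ($\ln 1.56$ for intermediate/high vs low, matching the estimand actually
  reported at group level; a per-allele term is available for sensitivity
  work) + BMI and age terms (CVD: 0.13 per kg/m², 0.09 per year; T2DM:
  0.12, 0.07 — chosen to reproduce the published AUC ordering
  age > BMI > GRS). The intercept is solved numerically against the
  realised covariates so the marginal prevalence hits its target (23.9%
  CVD, 5.4% T2DM) in expectation at any n. Note the *marginal* group OR
  under the default covariate effects is attenuated to ≈ 1.45–1.50 by
  non-collapsibility of the odds ratio; parameter-recovery checks therefore
  use a spec with covariate effects zeroed, where the cross-product OR is
  unbiased for the configured truth.
* **History and medications** are sampled *after* the statuses, so the
  classification rules recover the generated truth exactly; a configurable
  fraction of T2DM-negative records carries GLP-1 medication (some together
  with metformin) to exercise the override rule.
* **Determinism**: one master seed; each stage derives a sub-seed (all
  below $2^{31}$), so identical spec + seed gives bit-identical cohorts.

What passing tests on this generator show — and what they do not: they
validate the *estimators and plumbing* (scores, tables, ORs, CIs, CV and
bootstrap machinery, type-I error and coverage) under a faithful null and
alternative; they cannot validate the epidemiology of any real cohort,
which carries LD, genotyping error, self-report bias and confounding
structure the generator does not model.

## Numerical choices and degenerate inputs

* Stratum boundaries compared with tolerance $10^{-6}$ after the 2-decimal
  rescale, so attainable boundary scores classify stably.
* `grsScore` missing-dosage policies: `exclude` (default, conservative),
  `rescale` (score over available alleles), `mean_impute`; all-missing
  samples are always excluded; the policy is recorded in metadata.
* Monomorphic SNPs are flagged HWE-untestable instead of dividing by zero;
  HWE deviation is reported at 0.05 and Bonferroni 0.05/K, and no SNP is
  ever dropped automatically.
* Zero-IQR fence input removes nothing; fewer than 4 values is an error.
* Mann–Whitney uses exact enumeration for small untied samples and the
  tie-corrected normal approximation otherwise; Shapiro–Wilk on constant
  input is an error surfaced with a clear message.
* Degenerate single-sex cohorts drop the sex row of the descriptive table
  with a warning; an empty analysis group is an error.

## Problem sizes used by the test suite

The suite exercises full-size cohorts (n = 4279) where the claim depends on
scale — study emulation bands, stratum-OR recovery (200 replicates),
discrimination ordering (50 replicates) — and reduced designs elsewhere:
type-I error of the $\chi^2$ pipeline at n = 2000 over 1000 replicates, and
null-predictor bootstrap coverage at n = 400 with 100 bootstrap replicates
over 200 repetitions. These sizes keep each property estimable with useful
precision while the whole suite completes in a few minutes.

## Known limitations

* The BMI OR between GRS groups is intentionally not targeted: the
  published value (1.23) cannot be reconciled with its own group counts
  (cross-product 0.98 under the table's labelling), so the generator's
  small per-allele BMI slope yields a group OR near 1, and the forest
  output simply reports what the data give.
* Published CI bounds for the group ORs (e.g. 1.03–2.49 for T2DM) do not
  match Woolf intervals on the printed counts, suggesting covariate
  adjustment was involved; point estimates are the reproducible quantity,
  and intervals are always emitted with their method tag.
* The Gaussian age-matching scheme is one defensible reading of
  "approximating the Gaussian distribution of the reference class"; the
  exact published procedure (bin width, replacement) is unspecified.
* Self-reported outcomes are taken at face value; no clinical adjudication,
  T1DM separation or severity grading is attempted.
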