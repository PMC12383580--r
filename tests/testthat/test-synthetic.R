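test_that("genotype generator respects degenerate and HWE frequencies", {
  expect_true(all(genGenotypes(rep(0, 3), 50, seed = 1) == 0))
  expect_true(all(genGenotypes(rep(1, 3), 50, seed = 1) == 2))
  expect_error(genGenotypes(c(0.5, 1.2), 10, seed = 1), "\\[0,1\\]")

  # freq 0.5, n = 10000: genotype classes within 3 binomial SE of 1/4,1/2,1/4
  d <- genGenotypes(0.5, 10000, seed = 42)
  pr <- tabulate(d + 1L, 3) / 10000
  se <- sqrt(c(.25 * .75, .5 * .5, .25 * .75) / 10000)
  expect_true(all(abs(pr - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("simulation is bit-identical under a fixed seed", {
  s1 <- simulateCohort(cohortSpec(n = 200), seed = 7)
  s2 <- simulateCohort(cohortSpec(n = 200), seed = 7)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  s3 <- simulateCohort(cohortSpec(n = 200), seed = 8)
  expect_false(identical(s1$phenotypes$age, s3$phenotypes$age))
})

test_that("generated genotypes sit in HWE at the 0.001 level", {
  # 100 replicate cohorts x 18 SNPs at n = 4000: >= 99% of tests non-significant
  spec <- cohortSpec(n = 4000)
  reject <- 0L; total <- 0L
  for (r in 1:100) {
    g <- genGenotypes(spec$risk_allele_freqs, 4000, seed = 5000 + r)
    hw <- hweByLocus(g)
    reject <- reject + sum(hw$p_value < 0.001, na.rm = TRUE)
    total <- total + sum(hw$testable)
  }
  expect_gte(1 - reject / total, 0.99)
})

test_that("null outcome effects leave prevalence flat across GRS groups", {
  spec <- cohortSpec(n = 20000,
                     cvd_model = list(prevalence = 0.239, stratum_log_or = 0,
                                      allele_log_or = 0, bmi_log_or = 0,
                                      age_log_or = 0))
  sim <- simulateCohort(spec, seed = 12)
  tr <- attr(sim$phenotypes, "truth")
  se <- sqrt(0.239 * 0.761 / 20000)
  expect_lt(abs(mean(tr$cvd) - 0.239), 3 * se)
  byGrp <- tapply(tr$cvd, tr$analysis_group, mean)
  expect_lt(abs(diff(byGrp)), 4 * sqrt(0.239 * 0.761 / min(table(tr$analysis_group))))
})

test_that("a configured stratum odds ratio of 1.56 is recovered at n = 50000", {
  spec <- cohortSpec(n = 50000,
                     cvd_model = list(prevalence = 0.239,
                                      stratum_log_or = log(1.56),
                                      allele_log_or = 0, bmi_log_or = 0,
                                      age_log_or = 0))
  sim <- simulateCohort(spec, seed = 21)
  tr <- attr(sim$phenotypes, "truth")
  grp <- tr$analysis_group == "intermediate_high"
  t <- contingency2x2(sum(tr$cvd & grp), sum(!tr$cvd & grp),
                      sum(tr$cvd & !grp), sum(!tr$cvd & !grp))
  o <- oddsRatio(t)
  se <- sqrt(sum(1 / o$cells))
  expect_lt(abs(log(o$or) - log(1.56)), 3 * se)
})

test_that("age slope induces the intended positive age-BMI association", {
  sim <- simulateCohort(cohortSpec(n = 5000), seed = 33)
  ph <- sim$phenotypes
  bmi <- ph$weight_kg / ph$height_m^2
  ct <- suppressWarnings(cor.test(ph$age, bmi, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("study emulation reproduces the target descriptives at n = 4279", {
  es <- emulateStudy(seed = 1)
  cd <- colData(es$cohort)
  expect_equal(ncol(es$cohort), 4279L)
  expect_gt(mean(cd$t2dm), 0.034); expect_lt(mean(cd$t2dm), 0.074)
  expect_gt(mean(cd$sex == "F"), 0.734); expect_lt(mean(cd$sex == "F"), 0.774)
  expect_lt(abs(mean(cd$cvd) - 0.239), 0.02)
  expect_lt(abs(mean(cd$bmi >= 25) - 0.705), 0.02)
  expect_lt(abs(median(cd$age) - 41), 2)
  expect_lt(abs(median(cd$bmi) - 29.1), 1)
  # deterministic under the same seed
  es2 <- emulateStudy(seed = 1)
  expect_identical(colData(es$cohort), colData(es2$cohort))
})

test_that("generated medication lists exercise the GLP-1 override rule", {
  sim <- simulateCohort(cohortSpec(n = 8000, glp1_frac = 0.02,
                                   glp1_override_frac = 0.01), seed = 9)
  tr <- attr(sim$phenotypes, "truth")
  meds <- sim$phenotypes$medications
  hasGlp1 <- vapply(meds, function(m) "semaglutide" %in% m, logical(1))
  hasMet <- vapply(meds, function(m) "metformin" %in% m, logical(1))
  expect_gt(sum(!tr$t2dm & hasGlp1 & hasMet), 0)  # override cases exist
  # and the classifier recovers the generated statuses exactly
  cls <- classifyT2dm(sim$phenotypes$history, meds)
  expect_equal(cls$t2dm, tr$t2dm)
  clv <- classifyCvd(sim$phenotypes$history, meds)
  expect_equal(clv$cvd, tr$cvd)
})

test_that("simulation files round-trip through the standard readers", {
  sim <- simulateCohort(cohortSpec(n = 40, panel = testPanel(3),
                                   risk_allele_freqs = c(0.2, 0.4, 0.6)),
                        seed = 3)
  pre <- tempfile()
  paths <- writeSimulation(sim, pre)
  g <- readGenotypes(paths["genotypes"], testPanel(3))
  expect_identical(g, sim$genotypes)
  ph <- readPhenotypes(paths["phenotypes"])
  expect_equal(ph$sample_id, sim$phenotypes$sample_id)
  expect_equal(ph$age, sim$phenotypes$age, tolerance = 1e-6)
  expect_identical(ph$history, sim$phenotypes$history)
  tr <- jsonlite::fromJSON(paths["truth"])
  expect_equal(tr$seed, 3)
})
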