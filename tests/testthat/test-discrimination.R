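test_that("downsampling balances classes reproducibly", {
  y <- rep(c(TRUE, FALSE), c(30, 100))
  i <- downsampleBalance(y, seed = 1)
  expect_equal(sum(y[i]), 30)
  expect_equal(sum(!y[i]), 30)
  expect_identical(i, downsampleBalance(y, seed = 1))
  # already balanced input keeps every observation
  yb <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(sort(downsampleBalance(yb, seed = 2)), 1:40)
  # different seeds: different majority subsets, identical sizes
  i2 <- downsampleBalance(y, seed = 99)
  expect_equal(length(i2), length(i))
  expect_false(identical(i, i2))
  expect_error(downsampleBalance(rep(TRUE, 5)), "non-empty")
})

test_that("Gaussian age matching pulls the resampled class onto the reference", {
  set.seed(14)
  ageRef <- rnorm(1000, 30, 5)
  ageTgt <- rnorm(5000, 40, 8)   # shifted but overlapping support
  age <- c(ageRef, ageTgt)
  cls <- rep(c("ref", "tgt"), c(1000, 5000))
  idx <- gaussianAgeMatch(age, cls, target = "tgt", reference = "ref",
                          seed = 5)
  got <- idx[cls[idx] == "tgt"]
  expect_equal(length(got), 1000)
  expect_gt(mean(age[got]), 27); expect_lt(mean(age[got]), 33)
  expect_lt(abs(sd(age[got]) - 5), 0.1 * 5 + 0.5)

  # identical distributions: behaves like a plain subsample
  set.seed(15)
  ageT2 <- rnorm(5000, 30, 5)
  age2 <- c(ageRef, ageT2)
  idx2 <- gaussianAgeMatch(age2, cls, "tgt", "ref", seed = 6)
  got2 <- idx2[cls[idx2] == "tgt"]
  expect_lt(abs(mean(age2[got2]) - mean(ageT2)), 2 * sd(ageT2) / sqrt(1000))

  # disjoint support: warning reporting the achievable overlap
  age3 <- c(ageRef, rnorm(5000, 70, 3))
  expect_warning(gaussianAgeMatch(age3, cls, "tgt", "ref", seed = 7),
                 "support")
  expect_error(gaussianAgeMatch(rep(30, 2000), cls, "tgt", "ref", seed = 1),
               "degenerate")
})

test_that("single-predictor AUC equals Mann-Whitney concordance", {
  # perfectly separating predictor
  expect_equal(aucSinglePredictor(c(1, 2, 3, 10, 11, 12),
                                  c(0, 0, 0, 1, 1, 1)), 1)
  # constant predictor: 0.5 by the tie convention
  expect_equal(aucSinglePredictor(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  # shifted overlap, checked against explicit pair enumeration
  expect_equal(aucSinglePredictor(c(1, 2, 3, 4), c(0, 1, 0, 1)),
               concordanceOracle(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  expect_error(aucSinglePredictor(1:4, rep(1, 4)), "both outcome classes")

  # oracle equivalence whenever the fitted slope is non-negative
  set.seed(55)
  for (i in 1:500) {
    n <- sample(8:40, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    x <- rnorm(n) + y * runif(1, 0, 2)
    slope <- suppressWarnings(coef(glm(y ~ x, family = binomial()))["x"])
    if (is.na(slope) || slope < 0) next  # equivalence asserted for slope >= 0
    expect_equal(aucSinglePredictor(x, y), concordanceOracle(x, y),
                 tolerance = 1e-9)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (i in 1:20) {
    y <- sample(c(0, 1), 80, replace = TRUE)
    if (sum(y) < 2 || sum(1 - y) < 2) next
    x <- rnorm(80) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aucSinglePredictor(x, y), ref, tolerance = 1e-9)
  }
})

test_that("CV bootstrap AUC is seeded, powered and honors reduced settings", {
  set.seed(77)
  n <- 2000
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- rnorm(n) + ifelse(y, 1.47, 0)   # true AUC ~ 0.85
  r <- cvBootstrapAuc(x, y, nFolds = 10, nBoot = 200, seed = 3)
  expect_gt(r$auc, 0.8); expect_lt(r$auc, 0.9)
  expect_gt(r$ci_low, 0.5)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_equal(r$n_boot, 200)
  r2 <- cvBootstrapAuc(x, y, nFolds = 10, nBoot = 200, seed = 3)
  expect_identical(r, r2)
  # fold-AUC bootstrap variant runs and brackets its point estimate
  r3 <- cvBootstrapAuc(x, y, nFolds = 10, nBoot = 50, seed = 4,
                       bootMode = "fold_auc")
  expect_true(r3$ci_low <= r3$ci_high)
  expect_error(cvBootstrapAuc(rnorm(8), rep(c(TRUE, FALSE), 4), nFolds = 10,
                              nBoot = 10, seed = 1), "too few")
})

test_that("on emulated cohorts the GRS AUC for CVD is modest and below age", {
  hits <- 0L
  for (r in 1:50) {
    es <- emulateStudy(seed = 300 + r)
    coh <- scoreCohort(es$cohort)
    cd <- colData(coh)
    idx <- downsampleBalance(cd$cvd, seed = r)
    rep <- cardioGRS:::withSeed(400 + r, {
      grs <- cardioGRS:::cvMeanAuc(cd$grs_scaled[idx], cd$cvd[idx], 10)
      age <- cardioGRS:::cvMeanAuc(cd$age[idx], cd$cvd[idx], 10)
      c(grs = grs, age = age)
    })
    if (rep["grs"] >= 0.50 && rep["grs"] <= 0.57 && rep["age"] > rep["grs"])
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90% of 50 replicates
})

test_that("per-predictor AUC report reproduces the study's predictor ordering", {
  es <- emulateStudy(seed = 11)
  coh <- scoreCohort(es$cohort)
  rep <- aucReport(coh, "cvd", predictors = c("grs", "age", "bmi"),
                   nBoot = 50, seed = 2)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$ci_low <= rep$auc & rep$auc <= rep$ci_high))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  a <- setNames(rep$auc, rep$predictor)
  expect_gt(a["age"], a["grs"])
  expect_gt(a["bmi"], a["grs"])
})
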