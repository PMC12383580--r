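test_that("cross-product odds ratios reproduce hand computations", {
  # symmetric table
  expect_equal(oddsRatio(contingency2x2(10, 10, 10, 10))$or, 1)
  o <- oddsRatio(contingency2x2(914, 2746, 109, 510))
  expect_equal(round(o$or, 2), 1.56)
  expect_true(o$ci_low <= o$or && o$or <= o$ci_high)
  o2 <- oddsRatio(contingency2x2(209, 3451, 23, 596))
  expect_equal(round(o2$or, 2), 1.57)
  # Haldane-Anscombe correction on zero cells, flagged
  oz <- oddsRatio(contingency2x2(5, 0, 3, 7))
  expect_true(oz$haldane)
  expect_true(is.finite(oz$or) && oz$or > 0)
  expect_error(oddsRatio(contingency2x2(0, 5, 5, 0)), "cross pattern")
})

test_that("OR inverts under exposure swap; chi-square is swap-invariant", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(1:80, 4, replace = TRUE)
    t1 <- contingency2x2(k[1], k[2], k[3], k[4])
    t2 <- contingency2x2(k[3], k[4], k[1], k[2])  # exposure labels swapped
    expect_equal(oddsRatio(t1)$or, 1 / oddsRatio(t2)$or, tolerance = 1e-12)
    expect_equal(chiSquareTest(t1)$chi2, chiSquareTest(t2)$chi2,
                 tolerance = 1e-12)
    t3 <- contingency2x2(k[2], k[1], k[4], k[3])  # outcome columns swapped
    expect_equal(chiSquareTest(t1)$chi2, chiSquareTest(t3)$chi2,
                 tolerance = 1e-12)
  }
})

test_that("Woolf interval equals the single-predictor logistic Wald interval", {
  set.seed(23)
  for (i in 1:40) {
    k <- sample(2:60, 4, replace = TRUE)
    o <- oddsRatio(contingency2x2(k[1], k[2], k[3], k[4]))
    y <- c(rep(1, k[1]), rep(0, k[2]), rep(1, k[3]), rep(0, k[4]))
    x <- c(rep(1, k[1] + k[2]), rep(0, k[3] + k[4]))
    fit <- glm(y ~ x, family = binomial(),
               control = glm.control(epsilon = 1e-14, maxit = 100))
    expect_equal(o$or, unname(exp(coef(fit)["x"])), tolerance = 1e-6)
    se <- sqrt(diag(vcov(fit)))["x"]
    expect_equal(o$ci_low, unname(exp(coef(fit)["x"] - qnorm(0.975) * se)),
                 tolerance = 1e-6)
    expect_equal(o$ci_high, unname(exp(coef(fit)["x"] + qnorm(0.975) * se)),
                 tolerance = 1e-6)
  }
})

test_that("Pearson chi-square without continuity correction", {
  expect_equal(chiSquareTest(contingency2x2(20, 40, 10, 20))$chi2, 0)
  expect_equal(chiSquareTest(contingency2x2(20, 40, 10, 20))$p_value, 1)
  expect_lt(chiSquareTest(contingency2x2(914, 2746, 109, 510))$p_value, 0.001)
  expect_equal(chiSquareTest(contingency2x2(10, 10, 10, 10))$chi2, 0)
  expect_error(chiSquareTest(contingency2x2(0, 0, 5, 5)), "margin")
  # continuity correction available by flag and weaker
  expect_lt(chiSquareTest(contingency2x2(8, 2, 3, 9), correct = TRUE)$chi2,
            chiSquareTest(contingency2x2(8, 2, 3, 9))$chi2)
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  expect_equal(fisherExact(contingency2x2(1, 9, 9, 1)),
               fisherOracle(1, 9, 9, 1), tolerance = 1e-9)
  expect_equal(round(fisherOracle(1, 9, 9, 1), 4), 0.0011)
  expect_equal(fisherExact(contingency2x2(20, 40, 10, 20)), 1)
  expect_equal(fisherExact(contingency2x2(0, 5, 5, 0)),
               fisherOracle(0, 5, 5, 0), tolerance = 1e-9)
  set.seed(41)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    k <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    expect_equal(fisherExact(contingency2x2(k[1], k[2], k[3], k[4])),
                 fisherOracle(k[1], k[2], k[3], k[4]), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U: ties, separation and exact small-sample p", {
  x <- c(1, 2, 3, 4)
  r <- mannWhitney(x, x)
  expect_equal(r$U, length(x)^2 / 2)   # identical multisets: all ties
  expect_gt(r$p_value, 0.9)

  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 0.1)   # 2 / choose(6,3), exact enumeration
  expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("Shapiro-Wilk screening is calibrated and catches skew", {
  pNorm <- vapply(1:100, function(i) {
    set.seed(1000 + i); shapiroWilk(rnorm(500))$p_value
  }, numeric(1))
  expect_gte(mean(pNorm > 0.05), 0.90)
  pExp <- vapply(1:100, function(i) {
    set.seed(2000 + i); shapiroWilk(rexp(500))$p_value
  }, numeric(1))
  expect_gte(mean(pExp < 0.05), 0.99)
  expect_error(shapiroWilk(rep(1, 10)), "constant")
})

test_that("descriptive table mirrors the cohort and picks sensible tests", {
  es <- emulateStudy(seed = 4)
  coh <- scoreCohort(es$cohort)
  tab <- descriptiveTable(coh)
  expect_true(all(c("age_years", "bmi_kg_m2", "cvd_yes_no", "grs_scaled")
                  %in% tab$variable))
  cd <- colData(coh)
  expect_lt(abs(pct1(sum(cd$cvd), ncol(coh)) - 23.9), 2)
  # GRS distributions differ strongly between the groups by construction
  expect_lt(tab$p_value[tab$variable == "grs_scaled"], 0.001)
  expect_equal(tab$test[tab$variable == "grs_scaled"], "mann_whitney")
  # skewed BMI reported as median +/- IQR
  expect_equal(tab$test[tab$variable == "bmi_kg_m2"], "mann_whitney")
})

test_that("single-sex cohorts drop the sex row with a warning", {
  panel <- testPanel(2)
  ids <- sprintf("S%02d", 1:40)
  set.seed(8)
  d <- matrix(sample(0:2, 80, replace = TRUE), 40,
              dimnames = list(ids, rsids(panel)))
  d[1:20, ] <- 0L  # force both strata present
  ph <- testPhenotypes(ids, age = runif(40, 20, 60),
                       weight = runif(40, 50, 110), sex = "F")
  coh <- scoreCohort(derivePhenotypes(GrsCohort(d, ph, panel)))
  expect_warning(tab <- descriptiveTable(coh), "single-sex")
  expect_false("sex_m_f" %in% tab$variable)
})

test_that("forest data carries one oriented 2x2 odds ratio per outcome", {
  es <- emulateStudy(seed = 6)
  coh <- scoreCohort(es$cohort)
  f <- forestData(coh)
  expect_equal(f$outcome, c("overweight_obese", "t2dm", "cvd"))
  cd <- colData(coh)
  expect_equal(f$a[f$outcome == "cvd"],
               sum(cd$cvd & cd$analysis_group == "intermediate_high"))
  expect_equal(f$a + f$b + f$c + f$d, rep(ncol(coh), 3))
  expect_true(all(f$ci_low <= f$or & f$or <= f$ci_high))
})
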