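#' Build an exposure-by-outcome 2x2 table
#'
#' Orientation is explicit: \code{a} = exposed & outcome-positive, \code{b} =
#' exposed & outcome-negative, \code{c} = unexposed & outcome-positive,
#' \code{d} = unexposed & outcome-negative. In the GRS analysis the exposure
#' is the merged intermediate/high stratum versus low.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param exposure,outcome labels recorded with the table.
#' @return a \code{contingency2x2} object (2x2 matrix with orientation
#'   attributes).
#' @export
contingency2x2 <- function(a, b, c, d, exposure = "exposed",
                           outcome = "outcome") {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
              dimnames = list(c(exposure, paste0("not_", exposure)),
                              c("positive", "negative")))
  structure(m, class = c("contingency2x2", "matrix"),
            exposure = exposure, outcome = outcome)
}

cells2x2 <- function(t) {
  if (inherits(t, "contingency2x2") || (is.matrix(t) && all(dim(t) == 2)))
    c(a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2])
  else stop("expected a 2x2 table")
}

#' Cross-product odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c); the 95\% CI is the Woolf log-method interval
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)), identical to the Wald
#' interval of a single-binary-predictor logistic model. When any cell is 0
#' the Haldane-Anscombe 0.5 correction is applied to every cell (flagged in
#' the result); two zero cells in a cross pattern leave the OR undefined and
#' raise an error. The p-value comes from the uncorrected Pearson chi-square
#' test on the original counts.
#'
#' @param t a \code{\link{contingency2x2}} (or plain 2x2 matrix).
#' @param conf confidence level (default 0.95).
#' @return list: \code{or}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{method} (\code{"woolf_log"}), \code{haldane} (correction flag),
#'   and the \code{cells} used.
#' @examples
#' oddsRatio(contingency2x2(914, 2746, 109, 510))  # OR 1.56
#' @export
oddsRatio <- function(t, conf = 0.95) {
  k <- cells2x2(t)
  if ((k["a"] == 0 && k["d"] == 0) || (k["b"] == 0 && k["c"] == 0))
    stop("odds ratio undefined: zero cells in a cross pattern")
  haldane <- any(k == 0)
  kk <- if (haldane) k + 0.5 else k
  or <- (kk["a"] * kk["d"]) / (kk["b"] * kk["c"])
  se <- sqrt(sum(1 / kk))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- tryCatch(chiSquareTest(t)$p_value, error = function(e) NA_real_)
  list(or = unname(or), ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)), p_value = p,
       method = "woolf_log", haldane = haldane, cells = unname(k))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (no Yates continuity correction), df = 1; large
#' printed odds ratios in case-control tables match uncorrected
#' cross-products, and the correction is available by flag.
#'
#' @param t a \code{\link{contingency2x2}} or 2x2 matrix.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with \code{chi2}, \code{p_value}, \code{df}.
#' @export
chiSquareTest <- function(t, correct = FALSE) {
  m <- unclass(t)[1:2, 1:2]
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square test undefined: zero margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(res$statistic), p_value = res$p.value, df = 1L)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p summing hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param t a \code{\link{contingency2x2}} or 2x2 matrix.
#' @return two-sided p-value.
#' @export
fisherExact <- function(t) {
  m <- unclass(t)[1:2, 1:2]
  stats::fisher.test(m)$p.value
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' U statistic (number of (x, y) pairs with x ranking higher, ties counted
#' half) with an exact p-value for small untied samples and the
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric samples.
#' @return list with \code{U} and \code{p_value}.
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(res$statistic), p_value = res$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Used only to choose between mean +/- SD and median +/- IQR reporting in
#' the descriptive table.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with \code{W} and \code{p_value}.
#' @export
shapiroWilk <- function(x) {
  if (length(unique(x)) == 1L) stop("sample is constant; W undefined")
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p_value = res$p.value)
}

# expected-count rule: Fisher when any expected cell < 5, else chi-square
pickCategoricalTest <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(e < 5)) "fisher" else "chi_square"
}

catRow <- function(variable, pos, neg, grp, posLabel) {
  lowIdx <- grp == "low"
  m <- rbind(c(sum(pos & !lowIdx), sum(neg & !lowIdx)),
             c(sum(pos & lowIdx), sum(neg & lowIdx)))
  test <- pickCategoricalTest(m)
  p <- if (test == "fisher") fisherExact(m) else chiSquareTest(m)$p_value
  tot <- length(grp)
  data.frame(
    variable = variable,
    overall = paste0(fmtCountPct(sum(pos), tot), "/",
                     fmtCountPct(sum(neg), tot)),
    low = paste0(fmtCountPct(sum(pos & lowIdx), sum(lowIdx)), "/",
                 fmtCountPct(sum(neg & lowIdx), sum(lowIdx))),
    intermediate_high = paste0(fmtCountPct(sum(pos & !lowIdx), sum(!lowIdx)),
                               "/",
                               fmtCountPct(sum(neg & !lowIdx), sum(!lowIdx))),
    test = test, p_value = p, stringsAsFactors = FALSE)
}

contRow <- function(variable, x, grp) {
  normal <- tryCatch(shapiroWilk(if (length(x) > 5000)
    sample(x, 5000) else x)$p_value > 0.05, error = function(e) FALSE)
  lowIdx <- grp == "low"
  if (normal) {
    p <- stats::t.test(x[lowIdx], x[!lowIdx])$p.value
    fmt <- fmtMeanSd; test <- "t_test"
  } else {
    p <- mannWhitney(x[lowIdx], x[!lowIdx])$p_value
    fmt <- fmtMedIqr; test <- "mann_whitney"
  }
  data.frame(variable = variable, overall = fmt(x), low = fmt(x[lowIdx]),
             intermediate_high = fmt(x[!lowIdx]), test = test, p_value = p,
             stringsAsFactors = FALSE)
}

#' Descriptive characteristics table by GRS group
#'
#' Mirrors the classic "Table 2" of GRS case-control reports: age, sex, BMI,
#' BMI categories, T2DM, CVD, smoking and the rescaled GRS, summarised
#' overall and per analysis group (low vs intermediate/high). Continuous
#' variables are reported mean +/- SD or median +/- IQR depending on a
#' Shapiro-Wilk check, and compared by t-test or Mann-Whitney accordingly;
#' categorical variables use Pearson chi-square, or Fisher's exact test when
#' any expected cell is below 5. Proportions are printed to 1 decimal.
#'
#' @param x a scored, derived \code{\link{GrsCohort}}
#'   (\code{\link{derivePhenotypes}} + \code{\link{scoreCohort}}).
#' @return \code{data.frame} with one row per characteristic: formatted
#'   summaries, the test used and its p-value.
#' @export
descriptiveTable <- function(x) {
  cd <- colData(x)
  need <- c("bmi", "t2dm", "cvd", "analysis_group", "grs_scaled")
  if (!all(need %in% names(cd)))
    stop("cohort must be derived and scored first")
  grp <- cd$analysis_group
  if (length(unique(grp)) < 2) stop("need both analysis groups present")
  degenerateSex <- length(unique(cd$sex)) < 2
  rows <- list(
    contRow("age_years", cd$age, grp),
    if (!degenerateSex)
      catRow("sex_m_f", cd$sex == "M", cd$sex == "F", grp, "M"),
    contRow("bmi_kg_m2", cd$bmi, grp),
    catRow("bmi_overweight_obese", cd$bmi >= 25, cd$bmi < 25, grp, "ow"),
    catRow("t2dm_yes_no", cd$t2dm, !cd$t2dm, grp, "yes"),
    catRow("cvd_yes_no", cd$cvd, !cd$cvd, grp, "yes"),
    catRow("smoking_yes_no", cd$smoking == "yes", cd$smoking == "no", grp,
           "yes"),
    contRow("grs_scaled", cd$grs_scaled, grp))
  out <- do.call(rbind, rows)
  if (degenerateSex)
    warning("single-sex cohort: sex row omitted as degenerate")
  rownames(out) <- NULL
  out
}

#' Odds-ratio forest data for the standard outcomes
#'
#' One \code{\link{oddsRatio}} per outcome (overweight/obese, T2DM, CVD),
#' exposure = intermediate/high vs low GRS group, in the layout used for a
#' forest plot.
#'
#' @param x a scored, derived \code{\link{GrsCohort}}.
#' @return \code{data.frame}: outcome, cells a-d, or, ci_low, ci_high,
#'   p_value, haldane flag.
#' @export
forestData <- function(x) {
  cd <- colData(x)
  grp <- cd$analysis_group
  outcomes <- list(overweight_obese = cd$bmi >= 25,
                   t2dm = cd$t2dm, cvd = cd$cvd)
  rows <- lapply(names(outcomes), function(nm) {
    y <- outcomes[[nm]]
    t <- contingency2x2(sum(y & grp != "low"), sum(!y & grp != "low"),
                        sum(y & grp == "low"), sum(!y & grp == "low"),
                        exposure = "intermediate_high", outcome = nm)
    o <- oddsRatio(t)
    data.frame(outcome = nm, a = o$cells[1], b = o$cells[2], c = o$cells[3],
               d = o$cells[4], or = o$or, ci_low = o$ci_low,
               ci_high = o$ci_high, p_value = o$p_value,
               haldane = o$haldane, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
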