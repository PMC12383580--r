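# Rank-based concordance: P(x_case > x_control) + 0.5 P(tie).
concordanceAuc <- function(x, y) {
  y <- as.logical(y)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(x)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Randomly downsample the majority class
#'
#' Balances a binary outcome by sampling the overrepresented class without
#' replacement down to the size of the minority class.
#'
#' @param y logical (or 0/1) outcome vector.
#' @param seed integer seed.
#' @return integer indices of the retained observations (all minority
#'   members plus the sampled majority subset), in original order.
#' @export
downsampleBalance <- function(y, seed = NULL) {
  y <- as.logical(y)
  i1 <- which(y); i0 <- which(!y)
  if (!length(i1) || !length(i0)) stop("both outcome classes must be non-empty")
  withSeed(seed, {
    if (length(i1) > length(i0)) i1 <- sample(i1, length(i0))
    else if (length(i0) > length(i1)) i0 <- sample(i0, length(i1))
    sort(c(i1, i0))
  })
}

#' Gaussian age-matched resampling of a class
#'
#' Fits a Gaussian to the age distribution of the reference class, then
#' resamples the target class without replacement down to the reference
#' size, with weights proportional to the reference Gaussian density at each
#' member's age divided by the target class's empirical age density
#' (importance reweighting), so the resampled target approximates the
#' reference age distribution. The resampled target age mean and SD are
#' checked to lie within 10\% of the reference fit; a support mismatch
#' (target lacking members in part of the reference range) is reported with
#' a warning giving the achieved moments.
#'
#' @param age numeric age vector.
#' @param class vector of class labels aligned with \code{age}.
#' @param target label of the class to be resampled (typically the majority).
#' @param reference label of the class whose age distribution is matched.
#' @param seed integer seed.
#' @return integer indices: all reference members plus the resampled target
#'   subset.
#' @export
gaussianAgeMatch <- function(age, class, target, reference, seed = NULL) {
  iT <- which(class == target); iR <- which(class == reference)
  if (length(iT) < 30 || length(iR) < 30)
    stop("need at least 30 members per class to fit the Gaussian")
  mu <- mean(age[iR]); sdR <- stats::sd(age[iR])
  if (!is.finite(sdR) || sdR <= .Machine$double.eps)
    stop("degenerate age SD in reference class")
  dens <- stats::density(age[iT])
  fT <- stats::approx(dens$x, dens$y, xout = age[iT], rule = 2)$y
  w <- stats::dnorm(age[iT], mu, sdR) / pmax(fT, .Machine$double.eps)
  nOut <- min(length(iR), length(iT))
  idx <- withSeed(seed, iT[weightedSampleNoReplace(w, nOut)])
  mAch <- mean(age[idx]); sAch <- stats::sd(age[idx])
  if (abs(mAch - mu) > 0.1 * abs(mu) || abs(sAch - sdR) > 0.1 * sdR)
    warning(sprintf(paste0("age-matched resample reaches mean %.2f / SD %.2f",
                           " against reference fit %.2f / %.2f",
                           " (limited overlap in age support)"),
                    mAch, sAch, mu, sdR))
  sort(c(iR, idx))
}

# sequential weighted sampling without replacement (Chao-style via repeated
# draws on the remaining mass); n is small relative to weight vector here
weightedSampleNoReplace <- function(w, n) {
  sample(seq_along(w), n, replace = FALSE, prob = w)
}

#' Single-predictor logistic AUC
#'
#' Fits a one-variable logistic regression and computes the area under the
#' ROC curve of its fitted probabilities by the rank (midrank-tie) method.
#' Because the fitted probability is monotone in the predictor, the AUC of a
#' positively-sloped model equals the Mann-Whitney concordance of the
#' predictor itself. A constant predictor returns 0.5 by the tie convention.
#'
#' @param x numeric predictor.
#' @param y logical (or 0/1) outcome; both classes must be present.
#' @return AUC in [0, 1].
#' @export
aucSinglePredictor <- function(x, y) {
  y <- as.logical(y)
  if (!any(y) || all(y)) stop("both outcome classes must be present")
  if (length(unique(x)) == 1L) return(0.5)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), as.numeric(y),
                   family = stats::binomial()))
  # rank AUC on the linear predictor: same ordering as the fitted
  # probability, but immune to saturation collapsing distinct scores to 1.0
  concordanceAuc(fit$coefficients[2] * x, y)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratifiedFolds <- function(y, nFolds) {
  y <- as.logical(y)
  if (min(sum(y), sum(!y)) < nFolds)
    stop("too few members in a class for ", nFolds, "-fold stratification")
  f <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    i <- sample(which(y == cls))
    f[i] <- rep_len(seq_len(nFolds), length(i))
  }
  f
}

# mean out-of-fold AUC of a single-predictor logistic model
cvMeanAuc <- function(x, y, nFolds) {
  folds <- stratifiedFolds(y, nFolds)
  aucs <- vapply(seq_len(nFolds), function(k) {
    tr <- folds != k
    if (length(unique(x[tr])) == 1L) return(0.5)
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x[tr]), as.numeric(y[tr]),
                     family = stats::binomial()))
    concordanceAuc(fit$coefficients[2] * x[!tr], y[!tr])
  }, numeric(1))
  mean(aucs)
}

#' Cross-validated AUC with percentile bootstrap confidence interval
#'
#' Point estimate: mean out-of-fold AUC over stratified k-fold
#' cross-validation of the single-predictor logistic model. CI: percentile
#' 2.5/97.5 of the bootstrap distribution, where each replicate resamples
#' the (balanced) data with replacement within outcome class and recomputes
#' the CV-mean AUC. With \code{bootMode = "fold_auc"} the bootstrap instead
#' resamples the vector of per-fold AUCs of the original split (a cheaper,
#' more optimistic alternative).
#'
#' @param x numeric predictor (on balanced data; see
#'   \code{\link{downsampleBalance}} / \code{\link{gaussianAgeMatch}}).
#' @param y logical outcome.
#' @param nFolds folds (default 10).
#' @param nBoot bootstrap replicates (default 1000; reduce for quick runs).
#' @param seed integer seed driving fold assignment and bootstrap draws.
#' @param bootMode \code{"resample_data"} (default) or \code{"fold_auc"}.
#' @return list: \code{auc}, \code{ci_low}, \code{ci_high}, \code{n_folds},
#'   \code{n_boot}, \code{seed}, \code{boot_mode}.
#' @export
cvBootstrapAuc <- function(x, y, nFolds = 10, nBoot = 1000, seed = 1,
                           bootMode = c("resample_data", "fold_auc")) {
  bootMode <- match.arg(bootMode)
  y <- as.logical(y)
  withSeed(seed, {
    point <- cvMeanAuc(x, y, nFolds)
    i1 <- which(y); i0 <- which(!y)
    boot <- if (bootMode == "resample_data") {
      vapply(seq_len(nBoot), function(b) {
        idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
        cvMeanAuc(x[idx], y[idx], nFolds)
      }, numeric(1))
    } else {
      folds <- stratifiedFolds(y, nFolds)
      fa <- vapply(seq_len(nFolds), function(k) {
        tr <- folds != k
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, x[tr]), as.numeric(y[tr]),
                         family = stats::binomial()))
        concordanceAuc(fit$coefficients[2] * x[!tr], y[!tr])
      }, numeric(1))
      vapply(seq_len(nBoot), function(b)
        mean(sample(fa, replace = TRUE)), numeric(1))
    }
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
    list(auc = point, ci_low = ci[1], ci_high = ci[2], n_folds = nFolds,
         n_boot = nBoot, seed = seed, boot_mode = bootMode)
  })
}

#' Per-predictor AUC report for a cohort outcome
#'
#' Balances the cohort for the chosen outcome, then runs
#' \code{\link{cvBootstrapAuc}} for each requested predictor. Predictors are
#' taken from \code{colData}: \code{grs} (rescaled score), \code{age},
#' \code{bmi}, \code{sex} (male = 1), \code{smoking} (yes = 1), \code{t2dm}
#' / \code{cvd} (positive = 1). Balancing: \code{"downsample"} randomly
#' trims the majority class; \code{"gaussian_age_match"} resamples the
#' majority class to the age distribution of the minority (used for the
#' overweight/obese outcome where age imbalance inflates the age AUC);
#' \code{"none"} uses the cohort as-is.
#'
#' @param x a scored, derived \code{\link{GrsCohort}}.
#' @param outcome \code{"cvd"}, \code{"t2dm"} or \code{"overweight_obese"}.
#' @param predictors character vector of predictor names.
#' @param balance balancing method.
#' @param nFolds,nBoot,seed passed to \code{\link{cvBootstrapAuc}}.
#' @return \code{data.frame}, one row per predictor: auc, ci, settings.
#' @export
aucReport <- function(x, outcome = c("cvd", "t2dm", "overweight_obese"),
                      predictors = c("grs", "age", "bmi", "sex", "smoking"),
                      balance = c("downsample", "gaussian_age_match", "none"),
                      nFolds = 10, nBoot = 1000, seed = 1) {
  outcome <- match.arg(outcome)
  balance <- match.arg(balance)
  cd <- colData(x)
  y <- switch(outcome, cvd = cd$cvd, t2dm = cd$t2dm,
              overweight_obese = cd$bmi >= 25)
  y <- as.logical(y)
  idx <- switch(balance,
                downsample = downsampleBalance(y, seed),
                gaussian_age_match = gaussianAgeMatch(
                  cd$age, ifelse(y, "case", "control"),
                  target = if (sum(y) > sum(!y)) "case" else "control",
                  reference = if (sum(y) > sum(!y)) "control" else "case",
                  seed = seed),
                none = seq_along(y))
  predVals <- function(nm) switch(
    nm,
    grs = cd$grs_scaled, age = cd$age, bmi = cd$bmi,
    sex = as.numeric(cd$sex == "M"),
    smoking = as.numeric(cd$smoking == "yes"),
    t2dm = as.numeric(cd$t2dm), cvd = as.numeric(cd$cvd),
    stop("unknown predictor: ", nm))
  seeds <- subSeeds(seed, length(predictors))
  rows <- lapply(seq_along(predictors), function(i) {
    r <- cvBootstrapAuc(predVals(predictors[i])[idx], y[idx],
                        nFolds = nFolds, nBoot = nBoot, seed = seeds[i])
    data.frame(predictor = predictors[i], outcome = outcome, auc = r$auc,
               ci_low = r$ci_low, ci_high = r$ci_high, n = length(idx),
               n_folds = nFolds, n_boot = nBoot, balance = balance,
               seed = seeds[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
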