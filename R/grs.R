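#' Rescale a raw allele count to the 0-100 GRS scale
#'
#' The raw unweighted GRS is the number of risk alleles carried across the
#' K-SNP panel (0..2K; 0..36 for the default 18-SNP panel). For
#' interpretability it is rescaled to 0-100 as \code{100 * raw / (2K)} and
#' reported to 2 decimals, so e.g. raw 15 of 36 becomes 41.67 and raw 12
#' becomes 33.33.
#'
#' @param raw integer raw score(s) in 0..2K.
#' @param K panel size.
#' @return numeric rescaled score(s) in [0, 100], rounded to 2 decimals.
#' @export
rescaleGrs <- function(raw, K) {
  if (K < 1) stop("panel size must be >= 1")
  if (any(!is.na(raw) & (raw < 0 | raw > 2 * K)))
    stop("raw score out of range 0..2K")
  round(100 * raw / (2 * K), 2)
}

#' Tertile stratification of the rescaled GRS
#'
#' The 0-100 scale is cut into exact thirds: low up to and including 100/3,
#' high at and above 200/3, intermediate in between. The boundary values
#' attainable on an 18-SNP panel (33.33 = raw 12, 66.67 = raw 24) fall in
#' the low and high strata respectively, so in raw-allele space for K = 18
#' the strata are low <= 12, intermediate 13-23, high >= 24. For analysis the
#' intermediate and high strata are merged into one group.
#'
#' @param scaled rescaled score(s) in [0, 100].
#' @return \code{data.frame} with columns \code{stratum}
#'   (\code{low}/\code{intermediate}/\code{high}) and \code{analysis_group}
#'   (\code{low}/\code{intermediate_high}).
#' @export
stratifyGrs <- function(scaled) {
  if (any(!is.na(scaled) & (scaled < 0 | scaled > 100)))
    stop("scaled score out of range 0..100")
  tol <- 1e-6
  stratum <- ifelse(is.na(scaled), NA_character_,
                    ifelse(scaled <= 100 / 3 + tol, "low",
                           ifelse(scaled >= 200 / 3 - tol, "high",
                                  "intermediate")))
  data.frame(stratum = stratum,
             analysis_group = ifelse(stratum == "low", "low",
                                     "intermediate_high"),
             stringsAsFactors = FALSE)
}

#' Per-sample unweighted GRS from a dosage matrix
#'
#' Additive model: each risk allele contributes one point, so a sample's raw
#' score is the sum of its dosages. Missing dosages are handled per
#' \code{missingPolicy}: \code{"exclude"} (default) drops the sample (raw and
#' scaled become \code{NA} with \code{excluded = TRUE}),
#' \code{"rescale"} computes the score over the available SNPs and rescales
#' by the available maximum, and \code{"mean_impute"} substitutes each
#' missing dosage with the SNP's observed mean dosage. Samples with all
#' dosages missing are always excluded.
#'
#' @param dosages sample-by-SNP dosage matrix.
#' @param panel the \code{\link{SNPPanel}} (defines K).
#' @param missingPolicy one of \code{"exclude"}, \code{"rescale"},
#'   \code{"mean_impute"}.
#' @return \code{data.frame} with columns \code{raw}, \code{scaled},
#'   \code{stratum}, \code{analysis_group}, \code{n_missing},
#'   \code{excluded}; the policy is recorded as attribute
#'   \code{missing_policy}.
#' @export
grsScore <- function(dosages, panel,
                     missingPolicy = c("exclude", "rescale", "mean_impute")) {
  missingPolicy <- match.arg(missingPolicy)
  K <- panelSize(panel)
  if (ncol(dosages) != K) stop("dosage columns must match the panel")
  nMiss <- rowSums(is.na(dosages))
  allMiss <- nMiss == K
  raw <- rep(NA_real_, nrow(dosages))
  scaled <- rep(NA_real_, nrow(dosages))
  excluded <- allMiss
  if (missingPolicy == "exclude") {
    ok <- nMiss == 0
    excluded <- !ok
    raw[ok] <- rowSums(dosages[ok, , drop = FALSE])
    scaled[ok] <- rescaleGrs(raw[ok], K)
  } else if (missingPolicy == "rescale") {
    ok <- !allMiss
    avail <- K - nMiss
    raw[ok] <- rowSums(dosages[ok, , drop = FALSE], na.rm = TRUE)
    scaled[ok] <- round(100 * raw[ok] / (2 * avail[ok]), 2)
  } else {
    ok <- !allMiss
    colMean <- colMeans(dosages, na.rm = TRUE)
    imp <- dosages
    for (j in seq_len(K)) imp[is.na(imp[, j]), j] <- colMean[j]
    raw[ok] <- rowSums(imp[ok, , drop = FALSE])
    scaled[ok] <- rescaleGrs(raw[ok], K)
  }
  st <- stratifyGrs(scaled)
  out <- data.frame(raw = raw, scaled = scaled, stratum = st$stratum,
                    analysis_group = st$analysis_group, n_missing = nMiss,
                    excluded = excluded, stringsAsFactors = FALSE)
  rownames(out) <- rownames(dosages)
  attr(out, "missing_policy") <- missingPolicy
  out
}

#' Score a cohort and record GRS columns
#'
#' Runs \code{\link{grsScore}} on the cohort's dosages and stores
#' \code{grs_raw}, \code{grs_scaled}, \code{stratum} and
#' \code{analysis_group} in \code{colData}. Samples excluded by the missing
#' policy are dropped from the returned cohort and reported in
#' \code{metadata(x)$grs_excluded}.
#'
#' @inheritParams grsScore
#' @param x a \code{\link{GrsCohort}}.
#' @return the scored cohort (possibly fewer samples).
#' @export
scoreCohort <- function(x, missingPolicy = c("exclude", "rescale",
                                             "mean_impute")) {
  missingPolicy <- match.arg(missingPolicy)
  panel <- SNPPanel(rowData(x)$rsid, rowData(x)$gene, rowData(x)$risk_allele)
  sc <- grsScore(dosages(x), panel, missingPolicy)
  keep <- !sc$excluded
  out <- x[, keep]
  cd <- colData(out)
  cd$grs_raw <- sc$raw[keep]
  cd$grs_scaled <- sc$scaled[keep]
  cd$stratum <- sc$stratum[keep]
  cd$analysis_group <- sc$analysis_group[keep]
  colData(out) <- cd
  metadata(out)$grs_missing_policy <- missingPolicy
  metadata(out)$grs_excluded <- rownames(sc)[!keep]
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Chi-square goodness-of-fit against the genotype proportions p^2, 2pq, q^2
#' implied by allele counting, with 1 degree of freedom. Monomorphic SNPs
#' (only one allele observed) are flagged untestable rather than divided by
#' zero.
#'
#' @param n00 count of samples homozygous for the non-risk allele (dosage 0).
#' @param n01 heterozygote count (dosage 1).
#' @param n11 count homozygous for the risk allele (dosage 2).
#' @return one-row \code{data.frame}: observed counts, risk-allele frequency
#'   \code{p_risk}, expected counts, \code{chi2}, \code{p_value},
#'   \code{testable}.
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: chi2 = 0, p = 1
#' hweTest(50, 0, 50)    # maximal heterozygote deficit: chi2 = n
#' @export
hweTest <- function(n00, n01, n11) {
  n <- n00 + n01 + n11
  if (n < 1) stop("need at least one genotyped sample")
  q <- (2 * n11 + n01) / (2 * n)   # risk-allele frequency
  p <- 1 - q
  testable <- p > 0 && q > 0
  exp0 <- n * p^2; exp1 <- 2 * n * p * q; exp2 <- n * q^2
  if (testable) {
    chi2 <- (n00 - exp0)^2 / exp0 + (n01 - exp1)^2 / exp1 +
      (n11 - exp2)^2 / exp2
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_; pval <- NA_real_
  }
  data.frame(n00 = n00, n01 = n01, n11 = n11, n = n, p_risk = q,
             exp00 = exp0, exp01 = exp1, exp11 = exp2,
             chi2 = chi2, p_value = pval, testable = testable)
}

#' Per-SNP HWE tests on a cohort
#'
#' Tabulates dosages per panel SNP (missing calls dropped) and applies
#' \code{\link{hweTest}}. Reports the nominal 0.05 flag and a
#' Bonferroni-adjusted flag at 0.05/K; no SNP is dropped automatically.
#'
#' @param x a \code{\link{GrsCohort}} or sample-by-SNP dosage matrix.
#' @param alpha nominal significance level (default 0.05).
#' @return \code{data.frame}, one row per SNP, with \code{rsid}, the
#'   \code{\link{hweTest}} columns, and deviation flags \code{dev_nominal} /
#'   \code{dev_bonferroni}.
#' @export
hweByLocus <- function(x, alpha = 0.05) {
  d <- if (is(x, "GrsCohort")) dosages(x) else x
  K <- ncol(d)
  rows <- lapply(seq_len(K), function(j) {
    v <- d[, j]
    v <- v[!is.na(v)]
    hweTest(sum(v == 0), sum(v == 1), sum(v == 2))
  })
  out <- do.call(rbind, rows)
  out <- cbind(rsid = colnames(d), out, stringsAsFactors = FALSE)
  out$dev_nominal <- !is.na(out$p_value) & out$p_value < alpha
  out$dev_bonferroni <- !is.na(out$p_value) & out$p_value < alpha / K
  rownames(out) <- NULL
  out
}
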