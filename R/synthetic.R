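#' Specification of a synthetic case-control cohort
#'
#' Bundles every generator parameter with defaults calibrated to the
#' descriptive structure of a large adult nutrigenetics cohort: mostly
#' female (75.4%), median age about 41, left-skewed BMI with median about 29
#' and 70.5% overweight/obese, outcome prevalences 5.4% (T2DM) and 23.9%
#' (CVD), and a GRS-stratum odds ratio of 1.56 on both outcomes. Outcome
#' effects are applied at the stratum level (intermediate/high vs low) to
#' match the estimand such studies report; \code{allele_log_or} offers a
#' per-allele alternative for sensitivity work. Outcome model intercepts are
#' solved against the realized covariates so marginal prevalences match
#' their targets in expectation.
#'
#' @param n cohort size (default 4279).
#' @param panel \code{\link{SNPPanel}} (default: the shipped 18-SNP panel).
#' @param risk_allele_freqs per-SNP risk-allele frequencies in [0,1];
#'   defaults spread 0.25-0.60 so the raw-score median sits near 15/36.
#' @param female_fraction probability of sex F (default 0.754).
#' @param age_mean,age_sd,age_range normal age model, truncated to range.
#' @param bmi_model list: \code{intercept} (BMI at reference age/GRS),
#'   \code{age_slope} (kg/m^2 per year), \code{grs_slope} (kg/m^2 per risk
#'   allele), \code{noise_scale}, \code{skew} (signed log-normal shape;
#'   negative = left skew, 0 = Gaussian), \code{floor}.
#' @param t2dm_model,cvd_model lists: \code{prevalence} (marginal target),
#'   \code{stratum_log_or} (log-OR for intermediate/high vs low),
#'   \code{allele_log_or}, \code{bmi_log_or}, \code{age_log_or}.
#' @param smoking_prevalence probability of smoking yes (default 0.248).
#' @param glp1_frac fraction of T2DM-negative records carrying a GLP-1
#'   medication alone; \code{glp1_override_frac} adds metformin as well,
#'   exercising the medication-override classification rule.
#' @return a \code{cohortSpec} list (class \code{"cohortSpec"}).
#' @export
cohortSpec <- function(n = 4279,
                       panel = defaultPanel(),
                       risk_allele_freqs = seq(0.25, 0.60,
                                               length.out = panelSize(panel)),
                       female_fraction = 0.754,
                       age_mean = 41, age_sd = 8.6, age_range = c(18, 80),
                       bmi_model = list(intercept = 24.5, age_slope = 0.15,
                                        grs_slope = 0.05, noise_scale = 4.5,
                                        skew = -1.2, floor = 13),
                       t2dm_model = list(prevalence = 0.054,
                                         stratum_log_or = log(1.56),
                                         allele_log_or = 0,
                                         bmi_log_or = 0.12,
                                         age_log_or = 0.07),
                       cvd_model = list(prevalence = 0.239,
                                        stratum_log_or = log(1.56),
                                        allele_log_or = 0,
                                        bmi_log_or = 0.13,
                                        age_log_or = 0.09),
                       smoking_prevalence = 0.248,
                       glp1_frac = 0.01, glp1_override_frac = 0.003) {
  stopifnot(n >= 1,
            all(risk_allele_freqs >= 0 & risk_allele_freqs <= 1),
            length(risk_allele_freqs) == panelSize(panel),
            female_fraction >= 0 && female_fraction <= 1,
            t2dm_model$prevalence > 0 && t2dm_model$prevalence < 1,
            cvd_model$prevalence > 0 && cvd_model$prevalence < 1)
  structure(list(n = as.integer(n), panel = panel,
                 risk_allele_freqs = risk_allele_freqs,
                 female_fraction = female_fraction, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 bmi_model = bmi_model, t2dm_model = t2dm_model,
                 cvd_model = cvd_model,
                 smoking_prevalence = smoking_prevalence,
                 glp1_frac = glp1_frac,
                 glp1_override_frac = glp1_override_frac),
            class = "cohortSpec")
}

#' Generate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each SNP is drawn independently as Binomial(2, freq) -- unlinked loci in
#' HWE, no population structure.
#'
#' @param freqs per-SNP risk-allele frequencies in [0,1].
#' @param n number of samples.
#' @param seed integer seed (reproducible draws).
#' @param rsids optional column names (defaults to snp1..snpK).
#' @return sample-by-SNP integer dosage matrix.
#' @export
genGenotypes <- function(freqs, n, seed = NULL,
                         rsids = paste0("snp", seq_along(freqs))) {
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0,1]")
  withSeed(seed, {
    m <- vapply(freqs, function(f) stats::rbinom(n, 2L, f), integer(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    dimnames(m) <- list(sprintf("S%05d", seq_len(n)), rsids)
    m
  })
}

# signed log-normal noise: skew < 0 gives a long lower tail, 0 is Gaussian
skewNoise <- function(n, scale, skew) {
  if (skew == 0) return(stats::rnorm(n, 0, scale))
  s <- abs(skew)
  sign(skew) * scale * (exp(s * stats::rnorm(n)) - exp(s^2 / 2))
}

solveIntercept <- function(lp, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + lp)) - target,
                 c(-30, 30), tol = 1e-10)$root
}

#' Generate questionnaire phenotypes for a genotyped cohort
#'
#' Age is truncated-normal; BMI follows a linear model in age and raw GRS
#' with signed-lognormal noise; T2DM and CVD statuses are Bernoulli with
#' logits carrying the configured stratum-level (and optional per-allele)
#' GRS effect plus BMI/age terms; history flags and medication lists are
#' then sampled consistently with the statuses, including a configurable
#' fraction of GLP-1 users among T2DM-negative records.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param genotypes sample-by-SNP dosage matrix with \code{spec$n} rows.
#' @param seed integer seed.
#' @return phenotype \code{data.frame} (layout of
#'   \code{\link{readPhenotypes}}) with the realized latent truth
#'   (\code{grs_raw}, \code{analysis_group}, outcome probabilities) attached
#'   as attribute \code{"truth"}.
#' @export
genPhenotypes <- function(spec, genotypes, seed = NULL) {
  if (nrow(genotypes) != spec$n)
    stop("genotype sample count must equal spec$n")
  withSeed(seed, {
    n <- spec$n
    K <- panelSize(spec$panel)
    raw <- rowSums(genotypes)
    rawRef <- 2 * sum(spec$risk_allele_freqs)
    grp <- stratifyGrs(rescaleGrs(raw, K))$analysis_group
    isHigh <- grp == "intermediate_high"

    sex <- ifelse(stats::runif(n) < spec$female_fraction, "F", "M")
    age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                     spec$age_range[1]), spec$age_range[2])

    bm <- spec$bmi_model
    bmi <- bm$intercept + bm$age_slope * (age - spec$age_mean) +
      bm$grs_slope * (raw - rawRef) +
      skewNoise(n, bm$noise_scale, bm$skew)
    bmi <- pmax(bmi, bm$floor)

    height <- ifelse(sex == "F", stats::rnorm(n, 1.63, 0.065),
                     stats::rnorm(n, 1.77, 0.070))
    height <- pmin(pmax(height, 1.40), 2.10)
    weight <- bmi * height^2

    drawOutcome <- function(model) {
      lp <- model$stratum_log_or * isHigh +
        model$allele_log_or * (raw - rawRef) +
        model$bmi_log_or * (bmi - 29.09) +
        model$age_log_or * (age - 41)
      p <- stats::plogis(solveIntercept(lp, model$prevalence) + lp)
      list(status = stats::runif(n) < p, p = p)
    }
    t2 <- drawOutcome(spec$t2dm_model)
    cv <- drawOutcome(spec$cvd_model)

    smoking <- ifelse(stats::runif(n) < spec$smoking_prevalence, "yes", "no")

    history <- vector("list", n)
    meds <- vector("list", n)
    u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
    for (i in seq_len(n)) {
      h <- character(); m <- character()
      if (t2$status[i]) {
        h <- c(h, "t2dm")
        if (u1[i] < 0.5) m <- c(m, "metformin")
      } else if (u1[i] < spec$glp1_frac) {
        m <- c(m, "semaglutide")
      } else if (u1[i] < spec$glp1_frac + spec$glp1_override_frac) {
        m <- c(m, "metformin", "semaglutide")
      }
      if (cv$status[i]) {
        if (u2[i] < 0.8) {
          h <- c(h, sample(CVD_CONDITIONS, 1))
          if (u3[i] < 0.3) m <- c(m, sample(c("statin", "ace_inhibitor",
                                              "aspirin"), 1))
        } else {
          m <- c(m, sample(c("statin", "ace_inhibitor", "aspirin"), 1))
        }
      }
      history[[i]] <- h
      meds[[i]] <- m
    }

    out <- data.frame(sample_id = rownames(genotypes), age = age, sex = sex,
                      weight_kg = weight, height_m = height,
                      smoking = smoking, stringsAsFactors = FALSE)
    out$history <- history
    out$medications <- meds
    attr(out, "truth") <- data.frame(
      sample_id = rownames(genotypes), grs_raw = raw, analysis_group = grp,
      bmi = bmi, t2dm = t2$status, p_t2dm = t2$p, cvd = cv$status,
      p_cvd = cv$p, stringsAsFactors = FALSE)
    out
  })
}

#' Simulate a full synthetic cohort
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param seed master seed; every random stage derives its own sub-seed from
#'   it, so identical spec + seed gives bit-identical cohorts.
#' @return list with \code{genotypes} (dosage matrix), \code{phenotypes}
#'   (data.frame with \code{"truth"} attribute) and \code{spec}.
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1) {
  seeds <- subSeeds(seed, 2)
  g <- genGenotypes(spec$risk_allele_freqs, spec$n, seeds[1],
                    rsids = rsids(spec$panel))
  ph <- genPhenotypes(spec, g, seeds[2])
  list(genotypes = g, phenotypes = ph, spec = spec, seed = seed)
}

#' Emulate the reference study cohort
#'
#' Convenience wrapper: \code{\link{simulateCohort}} with the default
#' \code{\link{cohortSpec}} (n = 4279 and the calibrated descriptive
#' targets), assembled and phenotyped into a ready \code{\link{GrsCohort}}.
#'
#' @param seed master seed.
#' @param n cohort size (default 4279).
#' @return list: \code{cohort} (a derived, unscored \code{GrsCohort}),
#'   \code{sim} (the raw simulation), \code{assembly}
#'   (the \code{\link{CohortAssembly}}).
#' @export
emulateStudy <- function(seed = 1, n = 4279) {
  sim <- simulateCohort(cohortSpec(n = n), seed)
  asm <- assembleCohort(sim$genotypes, sim$phenotypes, sim$spec$panel,
                        bmiFilter = FALSE)
  list(cohort = cohort(asm), sim = sim, assembly = asm)
}

#' Write a simulated cohort to disk
#'
#' Writes \code{<prefix>_genotypes.tsv} (tabular dosage dialect),
#' \code{<prefix>_phenotypes.csv} and \code{<prefix>_truth.json} (generator
#' parameters, seed and realized latent values).
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
writeSimulation <- function(sim, prefix) {
  gp <- paste0(prefix, "_genotypes.tsv")
  pp <- paste0(prefix, "_phenotypes.csv")
  tp <- paste0(prefix, "_truth.json")
  writeGenotypes(sim$genotypes, gp)
  writePhenotypes(sim$phenotypes, pp)
  spec <- unclass(sim$spec)
  spec$panel <- panelTable(spec$panel)
  jsonlite::write_json(list(seed = sim$seed, spec = spec,
                            truth = attr(sim$phenotypes, "truth")),
                       tp, auto_unbox = TRUE, digits = NA)
  invisible(c(genotypes = gp, phenotypes = pp, truth = tp))
}
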