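#' Construct a GrsCohort from dosages and phenotypes
#'
#' @param dosages sample-by-SNP integer matrix of risk-allele dosages
#'   (rownames = sample IDs, colnames = panel rsIDs).
#' @param phenotypes \code{data.frame} in the layout of
#'   \code{\link{readPhenotypes}}, one row per sample in \code{dosages}.
#' @param panel the \code{\link{SNPPanel}} the dosage columns follow.
#' @return a \code{\link{GrsCohort}}.
#' @export
GrsCohort <- function(dosages, phenotypes, panel) {
  stopifnot(is(panel, "SNPPanel"))
  ids <- rownames(dosages)
  if (is.null(ids)) stop("dosage matrix must carry sample IDs as rownames")
  m <- match(ids, phenotypes$sample_id)
  if (anyNA(m)) stop("phenotypes missing for sample(s): ",
                     paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  ph <- phenotypes[m, , drop = FALSE]
  cd <- S4Vectors::DataFrame(
    age = ph$age, sex = ph$sex, weight_kg = ph$weight_kg,
    height_m = ph$height_m, smoking = ph$smoking,
    history = I(unname(ph$history)), medications = I(unname(ph$medications)),
    row.names = ids)
  rd <- S4Vectors::DataFrame(panelTable(panel), row.names = rsids(panel))
  se <- SummarizedExperiment(
    assays = list(dosage = t(dosages[, rsids(panel), drop = FALSE])),
    rowData = rd, colData = cd)
  new("GrsCohort", se)
}

#' @describeIn dosages sample-by-SNP dosage matrix of a cohort
#' @export
setMethod("dosages", "GrsCohort", function(x) t(assay(x, "dosage")))

setMethod("show", "GrsCohort", function(object) {
  cat("GrsCohort:", ncol(object), "samples x", nrow(object), "panel SNPs\n")
  derived <- intersect(c("bmi", "t2dm", "cvd", "grs_raw", "stratum"),
                       names(colData(object)))
  cat("  derived columns:",
      if (length(derived)) paste(derived, collapse = ", ") else "(none yet)",
      "\n")
  invisible(callNextMethod())
})

#' Derive BMI and outcome statuses on a cohort
#'
#' Adds to \code{colData}: \code{bmi}, \code{bmi_binary}, \code{bmi_three}
#' (from \code{\link{computeBmi}}), and \code{t2dm}/\code{cvd} statuses with
#' provenance (from \code{\link{classifyT2dm}} and \code{\link{classifyCvd}}).
#'
#' @param x a \code{\link{GrsCohort}}.
#' @param medMap medication-class map; see \code{\link{defaultMedicationMap}}.
#' @return the cohort with derived columns.
#' @export
derivePhenotypes <- function(x, medMap = defaultMedicationMap()) {
  cd <- colData(x)
  b <- computeBmi(cd$weight_kg, cd$height_m)
  t2 <- classifyT2dm(as.list(cd$history), as.list(cd$medications), medMap)
  cv <- classifyCvd(as.list(cd$history), as.list(cd$medications), medMap)
  cd$bmi <- b$bmi
  cd$bmi_binary <- b$binary_class
  cd$bmi_three <- b$three_class
  cd$t2dm <- t2$t2dm
  cd$t2dm_provenance <- t2$t2dm_provenance
  cd$cvd <- cv$cvd
  cd$cvd_provenance <- cv$cvd_provenance
  colData(x) <- cd
  x
}

#' Assemble an analysis cohort with exclusion bookkeeping
#'
#' Keeps the samples present in both the genotype and the phenotype input
#' (exact, case-sensitive ID match); genotyped samples without a
#' questionnaire are excluded as \code{missing_questionnaire}, questionnaire
#' samples without genotypes as \code{missing_genotype}. Phenotypes are then
#' derived and, when \code{bmiFilter} is \code{TRUE}, samples with BMI
#' outside the Tukey outer fences (computed once, on all matched samples)
#' are excluded as \code{bmi_outlier}. Each excluded sample carries exactly
#' one primary reason.
#'
#' @param genotypes sample-by-SNP dosage matrix (see
#'   \code{\link{readGenotypes}}).
#' @param phenotypes phenotype \code{data.frame}
#'   (see \code{\link{readPhenotypes}}).
#' @param panel the \code{\link{SNPPanel}}.
#' @param medMap medication-class map.
#' @param bmiFilter apply the BMI outer-fence filter (default \code{TRUE}).
#' @param fenceK fence multiplier passed to \code{\link{tukeyFences}}.
#' @return a \code{\link{CohortAssembly}}.
#' @export
assembleCohort <- function(genotypes, phenotypes, panel,
                           medMap = defaultMedicationMap(),
                           bmiFilter = TRUE, fenceK = 3) {
  gid <- rownames(genotypes)
  pid <- as.character(phenotypes$sample_id)
  common <- gid[gid %in% pid]
  if (length(common) == 0)
    stop("no samples present in both genotype and phenotype inputs")
  excl <- data.frame(sample_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  onlyG <- setdiff(gid, pid)
  onlyP <- setdiff(pid, gid)
  if (length(onlyG))
    excl <- rbind(excl, data.frame(sample_id = onlyG,
                                   reason = "missing_questionnaire"))
  if (length(onlyP))
    excl <- rbind(excl, data.frame(sample_id = onlyP,
                                   reason = "missing_genotype"))
  coh <- GrsCohort(genotypes[common, , drop = FALSE], phenotypes, panel)
  coh <- derivePhenotypes(coh, medMap)
  if (bmiFilter && ncol(coh) >= 4) {
    f <- tukeyFences(colData(coh)$bmi, k = fenceK)
    if (any(!f$keep)) {
      excl <- rbind(excl, data.frame(sample_id = colnames(coh)[!f$keep],
                                     reason = "bmi_outlier"))
      coh <- coh[, f$keep]
    }
    metadata(coh)$bmi_fences <- f$bounds
  }
  new("CohortAssembly", cohort = coh, excluded = excl,
      nInput = length(union(gid, pid)))
}

#' @describeIn cohort included cohort of an assembly
#' @export
setMethod("cohort", "CohortAssembly", function(x) x@cohort)

#' @describeIn excludedSamples exclusion ledger of an assembly
#' @export
setMethod("excludedSamples", "CohortAssembly", function(x) x@excluded)

#' @describeIn flowCounts sample-flow counts of an assembly
#' @export
setMethod("flowCounts", "CohortAssembly", function(x) {
  reasons <- c("missing_questionnaire", "missing_genotype", "bmi_outlier")
  cnt <- vapply(reasons, function(r) sum(x@excluded$reason == r), integer(1))
  c(input = x@nInput, included = ncol(x@cohort), cnt)
})

setMethod("show", "CohortAssembly", function(object) {
  fc <- flowCounts(object)
  cat("CohortAssembly:", fc["input"], "input samples,",
      fc["included"], "included\n")
  for (r in names(fc)[-(1:2)])
    cat(sprintf("  excluded (%s): %d\n", r, fc[[r]]))
})
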