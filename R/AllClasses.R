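#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData colData<-
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

#' SNP panel for an unweighted genetic risk score
#'
#' An \code{SNPPanel} holds the ordered set of biallelic SNPs contributing to
#' an additive genetic risk score, together with the configured risk allele of
#' each SNP (the allele counted 0/1/2 per genotype). Risk alleles are
#' configuration, not data: association studies typically print rsIDs and gene
#' labels but leave the risk-allele orientation to the genotyping panel.
#'
#' @slot snps a \code{data.frame} with columns \code{rsid}, \code{gene},
#'   \code{risk_allele} and optionally \code{ref}/\code{alt} (used to check
#'   orientation when reading VCF input).
#'
#' @seealso \code{\link{loadPanel}}, \code{\link{defaultPanel}}
#' @export
setClass("SNPPanel", representation(snps = "data.frame"))

setValidity("SNPPanel", function(object) {
  sn <- object@snps
  msgs <- character()
  need <- c("rsid", "gene", "risk_allele")
  if (!all(need %in% names(sn)))
    return(paste("panel table must have columns", paste(need, collapse = ", ")))
  if (nrow(sn) < 1) msgs <- c(msgs, "panel must contain at least one SNP")
  if (anyDuplicated(sn$rsid))
    msgs <- c(msgs, paste0("duplicated rsid: ",
                           paste(unique(sn$rsid[duplicated(sn$rsid)]), collapse = ", ")))
  bad <- !(sn$risk_allele %in% VALID_ALLELES)
  if (any(bad))
    msgs <- c(msgs, paste0("invalid risk allele for ",
                           paste(sn$rsid[bad], collapse = ", "),
                           " (must be one of A, C, G, T)"))
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Cohort container for GRS case-control analysis
#'
#' \code{GrsCohort} extends \code{SummarizedExperiment}: the \code{"dosage"}
#' assay stores risk-allele counts (0/1/2, \code{NA} when uncalled) with SNPs
#' as rows and samples as columns, \code{rowData} carries the panel
#' definition, and \code{colData} the questionnaire-derived phenotypes plus
#' any derived columns (\code{bmi}, outcome statuses, GRS columns) added by
#' \code{\link{derivePhenotypes}} and \code{\link{scoreCohort}}.
#'
#' @export
setClass("GrsCohort", contains = "SummarizedExperiment")

setValidity("GrsCohort", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("GrsCohort must carry a 'dosage' assay")
  d <- SummarizedExperiment::assay(object, "dosage")
  ok <- is.na(d) | d %in% c(0, 1, 2)
  if (!all(ok)) return("dosages must be 0, 1, 2 or NA")
  if (!"rsid" %in% names(rowData(object)))
    return("rowData must carry the panel (rsid column missing)")
  TRUE
})

#' Cohort assembly with exclusion bookkeeping
#'
#' Result of \code{\link{assembleCohort}}: the included cohort plus a ledger
#' of excluded samples, each with exactly one primary exclusion reason
#' (\code{missing_questionnaire}, \code{missing_genotype} or
#' \code{bmi_outlier}), mirroring the inclusion flowcharts of observational
#' genetic studies.
#'
#' @slot cohort the included samples as a \code{\link{GrsCohort}}.
#' @slot excluded \code{data.frame} with columns \code{sample_id}, \code{reason}.
#' @slot nInput number of distinct input samples (union of both sources).
#' @export
setClass("CohortAssembly",
         representation(cohort = "GrsCohort", excluded = "data.frame",
                        nInput = "integer"))

setValidity("CohortAssembly", function(object) {
  if (ncol(object@cohort) + nrow(object@excluded) != object@nInput)
    return("included + excluded must equal the number of input samples")
  okr <- object@excluded$reason %in%
    c("missing_questionnaire", "missing_genotype", "bmi_outlier")
  if (!all(okr)) return("unknown exclusion reason")
  TRUE
})
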