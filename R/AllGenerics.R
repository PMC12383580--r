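#' Number of SNPs in a panel
#'
#' @param x an \code{\link{SNPPanel}} or \code{\link{GrsCohort}}.
#' @return integer panel size K; the maximum attainable raw GRS is 2K.
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))

#' Risk alleles of a panel
#' @param x an \code{\link{SNPPanel}}.
#' @return named character vector of risk alleles, one per rsid.
#' @export
setGeneric("riskAlleles", function(x) standardGeneric("riskAlleles"))

#' rsIDs of a panel
#' @param x an \code{\link{SNPPanel}} or \code{\link{GrsCohort}}.
#' @return character vector of rsIDs in panel order.
#' @export
setGeneric("rsids", function(x) standardGeneric("rsids"))

#' Included cohort of an assembly
#' @param x a \code{\link{CohortAssembly}}.
#' @return the included \code{\link{GrsCohort}}.
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' Exclusion ledger of an assembly
#' @param x a \code{\link{CohortAssembly}}.
#' @return \code{data.frame} with columns \code{sample_id} and \code{reason}.
#' @export
setGeneric("excludedSamples", function(x) standardGeneric("excludedSamples"))

#' Sample-flow counts of an assembly
#' @param x a \code{\link{CohortAssembly}}.
#' @return named integer vector: \code{input}, \code{included}, and one count
#'   per exclusion reason.
#' @export
setGeneric("flowCounts", function(x) standardGeneric("flowCounts"))

#' Per-sample risk-allele dosages
#' @param x a \code{\link{GrsCohort}}.
#' @return sample-by-SNP integer matrix of dosages (transpose of the assay).
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
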