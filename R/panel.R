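#' Construct an SNP panel
#'
#' @param rsid character vector of rsIDs (unique).
#' @param gene character vector of gene labels (recycled if length 1).
#' @param risk_allele character vector of risk alleles, each one of
#'   \code{A,C,G,T}.
#' @param ref,alt optional reference/alternate alleles used to validate
#'   orientation against VCF input; \code{NA} when unknown.
#' @return an \code{\link{SNPPanel}}.
#' @examples
#' p <- SNPPanel(c("rs9939609", "rs17782313"), c("FTO", "MC4R"), c("A", "C"))
#' panelSize(p)
#' @export
SNPPanel <- function(rsid, gene = NA_character_, risk_allele,
                     ref = NA_character_, alt = NA_character_) {
  snps <- data.frame(rsid = as.character(rsid),
                     gene = rep_len(as.character(gene), length(rsid)),
                     risk_allele = toupper(as.character(risk_allele)),
                     ref = rep_len(as.character(ref), length(rsid)),
                     alt = rep_len(as.character(alt), length(rsid)),
                     stringsAsFactors = FALSE)
  new("SNPPanel", snps = snps)
}

#' Load an SNP panel from a configuration file
#'
#' Accepts either a JSON array of objects or a TSV with header; both need
#' fields \code{rsid}, \code{gene} (optional) and \code{risk_allele}, plus
#' optional \code{ref}/\code{alt}. File order is preserved.
#'
#' @param path path to a \code{.json} or \code{.tsv} panel file.
#' @return an \code{\link{SNPPanel}}.
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  if (!all(c("rsid", "risk_allele") %in% names(df)))
    stop("panel config must provide 'rsid' and 'risk_allele' columns")
  if (nrow(df) < 1) stop("panel config lists no SNPs")
  SNPPanel(rsid = df$rsid,
           gene = if ("gene" %in% names(df)) df$gene else NA_character_,
           risk_allele = df$risk_allele,
           ref = if ("ref" %in% names(df)) df$ref else NA_character_,
           alt = if ("alt" %in% names(df)) df$alt else NA_character_)
}

#' The default 18-SNP cardiometabolic panel
#'
#' Loads the panel shipped with the package: 18 SNPs in genes of metabolic and
#' appetite-regulation pathways (ACE, ADH1C, ADORA2A, ADRB2, APOC3, APOE,
#' CLOCK, CYP1A2, FADS2, FTO, LIPC, MC4R, MCM6, SLC2A2, TCF7L2). The risk
#' alleles in the shipped file are curated from the external GWAS literature
#' and are configuration, not measured data; edit the file or supply your own
#' panel via \code{\link{loadPanel}} to change the orientation.
#'
#' @return an \code{\link{SNPPanel}} with \code{panelSize} 18.
#' @export
defaultPanel <- function() {
  loadPanel(system.file("extdata", "default_panel.tsv",
                        package = "cardioGRS", mustWork = TRUE))
}

#' @describeIn panelSize panel size of an \code{SNPPanel}
#' @export
setMethod("panelSize", "SNPPanel", function(x) nrow(x@snps))

#' @describeIn panelSize panel size of a \code{GrsCohort} (number of assay rows)
#' @export
setMethod("panelSize", "GrsCohort", function(x) nrow(x))

#' @describeIn riskAlleles risk alleles of an \code{SNPPanel}
#' @export
setMethod("riskAlleles", "SNPPanel", function(x) {
  stats::setNames(x@snps$risk_allele, x@snps$rsid)
})

#' @describeIn rsids rsIDs of an \code{SNPPanel}
#' @export
setMethod("rsids", "SNPPanel", function(x) x@snps$rsid)

#' @describeIn rsids rsIDs of a \code{GrsCohort}
#' @export
setMethod("rsids", "GrsCohort", function(x) as.character(rowData(x)$rsid))

setMethod("show", "SNPPanel", function(object) {
  cat("SNPPanel with", panelSize(object), "SNPs (max raw score",
      2L * panelSize(object), ")\n")
  sn <- object@snps
  shown <- utils::head(sn, 6)
  cat(paste0("  ", shown$rsid, " [", shown$gene, "] risk=",
             shown$risk_allele, collapse = "\n"), "\n")
  if (nrow(sn) > 6) cat("  ...", nrow(sn) - 6, "more\n")
})

panelTable <- function(panel) panel@snps
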