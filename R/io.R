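#' Risk-allele dosage of a called genotype
#'
#' @param genotype character vector of two-letter genotype calls
#'   (e.g. \code{"AT"}); \code{NA} or \code{""} means uncalled.
#' @param risk_allele single risk allele per genotype (recycled).
#' @return integer dosage in 0..2, \code{NA} for uncalled genotypes.
#' @examples
#' dosageFromGenotype(c("AA", "AT", "TT", NA), "A")
#' @export
dosageFromGenotype <- function(genotype, risk_allele) {
  risk_allele <- rep_len(toupper(risk_allele), length(genotype))
  out <- rep(NA_integer_, length(genotype))
  called <- !is.na(genotype) & nzchar(genotype)
  if (any(called)) {
    g <- toupper(genotype[called])
    if (any(nchar(g) != 2L))
      stop("genotype calls must be two-letter strings, e.g. 'AT'")
    out[called] <- (substr(g, 1, 1) == risk_allele[called]) +
      (substr(g, 2, 2) == risk_allele[called])
  }
  out
}

#' Read a genotype dosage matrix
#'
#' Two input paths are supported. The tabular dialect is a tab-separated file
#' with a \code{sample_id} column and one column per rsID holding risk-allele
#' dosages 0/1/2 or \code{NA}. A VCF 4.x file is matched against the panel by
#' the ID column; the dosage is the count of the configured risk allele in
#' the GT field, so the risk allele must be one of REF/ALT (otherwise an
#' error names the offending rsID). Multi-allelic records for panel SNPs are
#' rejected; uncalled genotypes (\code{./.}) become \code{NA}. Panel SNPs
#' absent from the input yield an all-missing column with a warning.
#'
#' @param path path to a \code{.tsv}/\code{.txt} dosage file or a \code{.vcf}.
#' @param panel an \code{\link{SNPPanel}}; column order of the result follows
#'   the panel.
#' @return integer matrix, samples in rows (rownames = sample IDs), panel
#'   SNPs in columns.
#' @export
readGenotypes <- function(path, panel) {
  stopifnot(is(panel, "SNPPanel"))
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    readGenotypesVcf(path, panel)
  } else {
    readGenotypesTsv(path, panel)
  }
}

readGenotypesTsv <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("dosage file must have a 'sample_id' column")
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) stop("duplicated sample_id in dosage file")
  out <- matrix(NA_integer_, nrow = nrow(df), ncol = panelSize(panel),
                dimnames = list(ids, rsids(panel)))
  for (rs in rsids(panel)) {
    if (!rs %in% names(df)) {
      warning("panel SNP ", rs, " absent from dosage file; column set to missing")
      next
    }
    v <- df[[rs]]
    v[v %in% c("NA", "")] <- NA
    v <- as.integer(v)
    if (any(!is.na(v) & !(v %in% 0:2)))
      stop("dosages for ", rs, " must be 0, 1, 2 or NA")
    out[, rs] <- v
  }
  out
}

readGenotypesVcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  out <- matrix(NA_integer_, nrow = length(samples), ncol = panelSize(panel),
                dimnames = list(samples, rsids(panel)))
  ra <- riskAlleles(panel)
  for (rs in rsids(panel)) {
    i <- which(fix[, "ID"] == rs)
    if (length(i) == 0) {
      warning("panel SNP ", rs, " absent from VCF; column set to missing")
      next
    }
    if (length(i) > 1) stop("multiple VCF records for ", rs)
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (grepl(",", alt, fixed = TRUE))
      stop("multi-allelic VCF record for panel SNP ", rs, " not supported")
    alleles <- c(ref, alt)
    if (!ra[[rs]] %in% alleles)
      stop("configured risk allele ", ra[[rs]], " for ", rs,
           " matches neither REF (", ref, ") nor ALT (", alt, ")")
    riskIdx <- as.character(which(alleles == ra[[rs]]) - 1L)
    calls <- gt[i, samples]
    parts <- strsplit(calls, "[/|]")
    out[, rs] <- vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".") || anyNA(p)) return(NA_integer_)
      sum(p == riskIdx)
    }, integer(1))
  }
  out
}

#' Write a genotype dosage matrix in the tabular dialect
#'
#' Round-trips with \code{\link{readGenotypes}}: missing dosages are written
#' as \code{NA}.
#'
#' @param dosages sample-by-SNP dosage matrix with dimnames.
#' @param path output path.
#' @export
writeGenotypes <- function(dosages, path) {
  df <- data.frame(sample_id = rownames(dosages), dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a questionnaire-derived phenotype table
#'
#' CSV with header \code{sample_id,age,sex,weight_kg,height_m,smoking,history,
#' medications}; \code{history} and \code{medications} are semicolon-separated
#' label lists (empty for none). Sex is \code{M}/\code{F}; smoking is
#' \code{yes}/\code{no}.
#'
#' @param path path to the CSV.
#' @return \code{data.frame} with list-columns \code{history} and
#'   \code{medications}.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  need <- c("sample_id", "age", "sex", "weight_kg", "height_m",
            "smoking", "history", "medications")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in phenotype file")
  df$history <- semicolonSplit(as.character(df$history))
  df$medications <- semicolonSplit(as.character(df$medications))
  df
}

#' Write a phenotype table
#' @param phenotypes \code{data.frame} as returned by
#'   \code{\link{readPhenotypes}} (list-columns allowed).
#' @param path output CSV path.
#' @export
writePhenotypes <- function(phenotypes, path) {
  df <- phenotypes[, c("sample_id", "age", "sex", "weight_kg", "height_m",
                       "smoking", "history", "medications")]
  df$history <- semicolonJoin(df$history)
  df$medications <- semicolonJoin(df$medications)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
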