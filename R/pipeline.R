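#' End-to-end analysis pipeline
#'
#' Runs the full chain -- simulate or ingest a cohort, assemble with
#' exclusion bookkeeping, derive phenotypes, score the GRS, test per-SNP
#' HWE, build the descriptive table, odds-ratio forest data and AUC reports
#' -- and writes a machine-readable bundle to \code{outDir}:
#' \code{cohort_flow.json}, \code{table2.tsv}, \code{forest_or.tsv},
#' \code{auc_report.tsv}, \code{hwe.tsv}, plus \code{run_config.json} (config
#' echo, seeds, panel checksum, package version) and \code{run_log.txt}.
#'
#' @param genotypes path to a dosage TSV / VCF, or a dosage matrix; ignored
#'   when \code{simulate} is given.
#' @param phenotypes path to a phenotype CSV, or a data.frame; ignored when
#'   \code{simulate} is given.
#' @param simulate optional \code{\link{cohortSpec}} -- when supplied the
#'   input cohort is generated with it instead of read from disk.
#' @param panel an \code{\link{SNPPanel}} (default: shipped panel).
#' @param medMap medication-class map.
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param seed master seed for every stochastic stage.
#' @param missingPolicy GRS missing-dosage policy.
#' @param aucOutcomes outcomes for the AUC stage.
#' @param balance balancing method for the AUC stage (the overweight/obese
#'   outcome always uses Gaussian age matching, as its imbalance is an age
#'   imbalance).
#' @param nFolds,nBoot cross-validation folds and bootstrap replicates.
#' @return invisibly, a list with every intermediate object (assembly,
#'   cohort, hwe, table2, forest, auc, paths).
#' @export
runPipeline <- function(genotypes = NULL, phenotypes = NULL, simulate = NULL,
                        panel = defaultPanel(),
                        medMap = defaultMedicationMap(), outDir = NULL,
                        seed = 1, missingPolicy = "exclude",
                        aucOutcomes = c("cvd", "t2dm", "overweight_obese"),
                        balance = "downsample", nFolds = 10, nBoot = 1000) {
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))

  if (!is.null(simulate)) {
    sim <- simulateCohort(simulate, seed)
    genotypes <- sim$genotypes
    phenotypes <- sim$phenotypes
    panel <- simulate$panel
    say("simulated cohort: n = ", simulate$n, ", seed = ", seed)
  }
  if (is.character(genotypes)) genotypes <- readGenotypes(genotypes, panel)
  if (is.character(phenotypes)) phenotypes <- readPhenotypes(phenotypes)

  asm <- assembleCohort(genotypes, phenotypes, panel, medMap)
  fc <- flowCounts(asm)
  say("assembly: ", paste(names(fc), fc, sep = "=", collapse = ", "))

  coh <- scoreCohort(cohort(asm), missingPolicy)
  say("scored ", ncol(coh), " samples (missing policy: ", missingPolicy, ")")

  hwe <- hweByLocus(coh)
  say(sum(hwe$dev_nominal), " SNP(s) deviate from HWE at 0.05 (",
      sum(hwe$dev_bonferroni), " after Bonferroni)")

  tab2 <- descriptiveTable(coh)
  forest <- forestData(coh)
  seeds <- subSeeds(seed + 1L, length(aucOutcomes))
  auc <- do.call(rbind, lapply(seq_along(aucOutcomes), function(i) {
    bal <- if (aucOutcomes[i] == "overweight_obese")
      "gaussian_age_match" else balance
    aucReport(coh, aucOutcomes[i], balance = bal, nFolds = nFolds,
              nBoot = nBoot, seed = seeds[i])
  }))

  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    jsonlite::write_json(as.list(fc), p("cohort_flow.json"),
                         auto_unbox = TRUE)
    utils::write.table(tab2, p("table2.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(forest, p("forest_or.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(auc, p("auc_report.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(hwe, p("hwe.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, missing_policy = missingPolicy, balance = balance,
           n_folds = nFolds, n_boot = nBoot,
           panel_checksum = panelChecksum(panel),
           package_version = as.character(utils::packageVersion("cardioGRS"))),
      p("run_config.json"), auto_unbox = TRUE)
    writeLines(log, p("run_log.txt"))
    paths <- vapply(c("cohort_flow.json", "table2.tsv", "forest_or.tsv",
                      "auc_report.tsv", "hwe.tsv"), p, character(1))
  }
  invisible(list(assembly = asm, cohort = coh, hwe = hwe, table2 = tab2,
                 forest = forest, auc = auc, flow = fc, log = log,
                 paths = paths))
}

# md5 of the canonical panel text, embedded in every report bundle
panelChecksum <- function(panel) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  utils::write.table(panelTable(panel), tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  unname(tools::md5sum(tf))
}
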