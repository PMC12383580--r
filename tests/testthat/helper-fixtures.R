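# Shared fixtures: small explicit panels, in-code file fixtures, oracles.

suppressMessages({
  library(SummarizedExperiment)
})

testPanel <- function(K = 3) {
  SNPPanel(rsid = paste0("rs", seq_len(K)),
           gene = paste0("GENE", seq_len(K)),
           risk_allele = rep(c("A", "C", "G", "T"), length.out = K))
}

# small deterministic phenotype table
testPhenotypes <- function(ids, age = 40, weight = 80, height = 1.7,
                           sex = "F", smoking = "no",
                           history = list(character()),
                           medications = list(character())) {
  n <- length(ids)
  df <- data.frame(sample_id = ids, age = rep_len(age, n),
                   sex = rep_len(sex, n),
                   weight_kg = rep_len(weight, n),
                   height_m = rep_len(height, n),
                   smoking = rep_len(smoking, n),
                   stringsAsFactors = FALSE)
  df$history <- rep_len(history, n)
  df$medications <- rep_len(medications, n)
  df
}

testDosages <- function(ids, K = 3, value = 1L) {
  m <- matrix(as.integer(value), nrow = length(ids), ncol = K,
              dimnames = list(ids, paste0("rs", seq_len(K))))
  m
}

writeTestVcf <- function(path, ids = c("rs1", "rs2"),
                         ref = c("A", "C"), alt = c("T", "G"),
                         gt = rbind(c("0/0", "0/1", "1/1", "./."),
                                    c("0/1", "1|1", "0/0", "0/0")),
                         samples = paste0("P", seq_len(ncol(gt)))) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(ids), function(i) {
    paste(c("1", as.character(100 * i), ids[i], ref[i], alt[i], ".", "PASS",
            ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# full hypergeometric enumeration oracle for the two-sided Fisher p
fisherOracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  pObs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# first-principles HWE chi-square from genotype counts
hweOracle <- function(n00, n01, n11) {
  n <- n00 + n01 + n11
  q <- (2 * n11 + n01) / (2 * n)
  p <- 1 - q
  e <- c(n * p^2, 2 * n * p * q, n * q^2)
  o <- c(n00, n01, n11)
  sum((o - e)^2 / e)
}

# concordance count by explicit pair enumeration
concordanceOracle <- function(x, y) {
  y <- as.logical(y)
  xc <- x[y]; xn <- x[!y]
  tot <- 0
  for (v in xc) tot <- tot + sum(v > xn) + 0.5 * sum(v == xn)
  tot / (length(xc) * length(xn))
}
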