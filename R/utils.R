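# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of sub-seeds from one master seed (keeps values < 2^31).
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# "count (pct)" display used by the descriptive table; proportions to 1 dp.
fmtCountPct <- function(count, total) {
  sprintf("%d (%.1f)", count, 100 * count / total)
}

#' Proportion as a percentage to 1 decimal place
#'
#' The display convention used throughout the report tables
#' (e.g. 3018 of 4279 prints as 70.5).
#'
#' @param count numerator count.
#' @param total denominator count.
#' @return percentage rounded to 1 decimal.
#' @export
pct1 <- function(count, total) round(100 * count / total, 1)

# "median +/- IQR" display for non-normal continuous variables
fmtMedIqr <- function(x) sprintf("%.2f ± %.2f",
                                 stats::median(x, na.rm = TRUE),
                                 stats::IQR(x, na.rm = TRUE))

fmtMeanSd <- function(x) sprintf("%.2f ± %.2f",
                                 mean(x, na.rm = TRUE),
                                 stats::sd(x, na.rm = TRUE))

semicolonSplit <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}

semicolonJoin <- function(lst) vapply(lst, paste, character(1), collapse = ";")
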