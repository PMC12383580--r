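#' Body mass index and weight-status categories
#'
#' BMI = weight / height^2 (kg/m^2). The binary classification merges
#' overweight and obese: normal-weight below 25 kg/m^2, overweight/obese at
#' or above. The three-class version splits overweight (25 to <30) from
#' obese (>= 30).
#'
#' @param weight_kg body weight in kilograms (> 0).
#' @param height_m standing height in metres (> 0).
#' @return \code{data.frame} with columns \code{bmi}, \code{binary_class}
#'   (\code{normal}/\code{overweight_obese}) and \code{three_class}
#'   (\code{normal}/\code{overweight}/\code{obese}).
#' @examples
#' computeBmi(72.25, 1.70)  # exactly at the 25 boundary -> overweight
#' @export
computeBmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive")
  bmi <- weight_kg / height_m^2
  data.frame(
    bmi = bmi,
    binary_class = ifelse(bmi >= 25, "overweight_obese", "normal"),
    three_class = ifelse(bmi >= 30, "obese",
                         ifelse(bmi >= 25, "overweight", "normal")),
    stringsAsFactors = FALSE)
}

#' Tukey outer-fence outlier filter
#'
#' Computes hinge quartiles (Tukey's median-of-halves convention, as drawn by
#' boxplots) on the full input once, sets fences at Q1 - k*IQR and
#' Q3 + k*IQR, and removes values strictly outside them. The default
#' multiplier k = 3 gives the outer fences used for extreme outliers in
#' skewed distributions; k = 1.5 gives the ordinary inner fences.
#'
#' @param values numeric vector, at least 4 values.
#' @param k fence multiplier (default 3, the outer fences).
#' @param quartiles \code{"hinges"} (default, Tukey hinges via
#'   \code{\link[stats]{fivenum}}) or \code{"type7"} (the
#'   \code{\link[stats]{quantile}} default convention).
#' @return list with \code{kept}, \code{removed}, \code{keep} (logical index
#'   into the input) and \code{bounds} (named vector q1, q3, iqr,
#'   lower_fence, upper_fence); the quartile convention is recorded as an
#'   attribute of \code{bounds}.
#' @export
tukeyFences <- function(values, k = 3, quartiles = c("hinges", "type7")) {
  quartiles <- match.arg(quartiles)
  if (length(values) < 4) stop("need at least 4 values to place fences")
  if (anyNA(values)) stop("values must not contain NA")
  if (quartiles == "hinges") {
    fn <- stats::fivenum(values)
    q1 <- fn[2]; q3 <- fn[4]
  } else {
    qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
    q1 <- qs[1]; q3 <- qs[2]
  }
  iqr <- q3 - q1
  lower <- q1 - k * iqr
  upper <- q3 + k * iqr
  keep <- values >= lower & values <= upper
  bounds <- c(q1 = q1, q3 = q3, iqr = iqr,
              lower_fence = lower, upper_fence = upper)
  attr(bounds, "quartiles") <- quartiles
  list(kept = values[keep], removed = values[!keep], keep = keep,
       bounds = bounds)
}

#' Default medication-class map
#'
#' Reads the editable lexicon shipped with the package, mapping free-text
#' medication labels to the classes used by the outcome rules:
#' \code{insulin}, \code{metformin}, \code{sulfonylurea},
#' \code{glp1_or_weightloss}, \code{antihypertensive}, \code{lipid_lowering},
#' \code{antiplatelet_anticoagulant}, \code{other}.
#'
#' @return named character vector label -> class.
#' @export
defaultMedicationMap <- function() {
  readMedicationMap(system.file("extdata", "medication_map.tsv",
                                package = "cardioGRS", mustWork = TRUE))
}

#' Read a medication-class map
#' @param path TSV with two columns, \code{label} and \code{class}.
#' @return named character vector label -> class.
#' @export
readMedicationMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("label", "class") %in% names(df)))
  stats::setNames(df$class, df$label)
}

MED_T2DM <- c("insulin", "metformin", "sulfonylurea")
MED_CVD <- c("antihypertensive", "lipid_lowering", "antiplatelet_anticoagulant")
CVD_CONDITIONS <- c("hypertension", "coronary_artery_disease", "stroke",
                    "dyslipidemia")

mapMeds <- function(medications, medMap) {
  lapply(medications, function(meds) {
    if (!length(meds)) return(character())
    cls <- unname(medMap[meds])
    unknown <- is.na(cls)
    if (any(unknown)) {
      warning("unknown medication label(s) ",
              paste(meds[unknown], collapse = ", "), "; classified as 'other'")
      cls[unknown] <- "other"
    }
    cls
  })
}

#' Classify type 2 diabetes status from self-report and medication
#'
#' A record is T2DM-positive when its history carries a \code{t2dm} flag, or
#' when it uses any glucose-lowering medication (insulin, metformin or a
#' sulfonylurea). Medication-only evidence is overridden to negative when the
#' record also carries a GLP-1 receptor agonist or a weight-loss prescription
#' (\code{glp1_or_weightloss} class): that rule exists to keep weight-loss
#' users without diabetes out of the case group. A positive history always
#' wins over the override.
#'
#' @param history list of character vectors of condition labels (one element
#'   per record), or a single character vector for one record.
#' @param medications list of character vectors of medication labels.
#' @param medMap named vector label -> class; see
#'   \code{\link{defaultMedicationMap}}.
#' @return \code{data.frame} with columns \code{t2dm} (logical) and
#'   \code{t2dm_provenance} (\code{history}/\code{medication}/
#'   \code{override}/\code{none}).
#' @export
classifyT2dm <- function(history, medications, medMap = defaultMedicationMap()) {
  if (!is.list(history)) history <- list(history)
  if (!is.list(medications)) medications <- list(medications)
  cls <- mapMeds(medications, medMap)
  hasHist <- vapply(history, function(h) "t2dm" %in% h, logical(1))
  hasMed <- vapply(cls, function(m) any(m %in% MED_T2DM), logical(1))
  hasGlp1 <- vapply(cls, function(m) "glp1_or_weightloss" %in% m, logical(1))
  status <- hasHist | (hasMed & !hasGlp1)
  prov <- ifelse(hasHist, "history",
                 ifelse(hasMed & !hasGlp1, "medication",
                        ifelse(hasMed & hasGlp1, "override", "none")))
  data.frame(t2dm = status, t2dm_provenance = prov, stringsAsFactors = FALSE)
}

#' Classify cardiovascular-trait status from self-report and medication
#'
#' Positive when the history carries any of hypertension, coronary artery
#' disease, stroke or dyslipidemia, and/or the record uses any cardiovascular
#' medication class (antihypertensive, lipid-lowering,
#' antiplatelet/anticoagulant).
#'
#' @inheritParams classifyT2dm
#' @return \code{data.frame} with columns \code{cvd} (logical) and
#'   \code{cvd_provenance}.
#' @export
classifyCvd <- function(history, medications, medMap = defaultMedicationMap()) {
  if (!is.list(history)) history <- list(history)
  if (!is.list(medications)) medications <- list(medications)
  cls <- mapMeds(medications, medMap)
  hasHist <- vapply(history, function(h) any(h %in% CVD_CONDITIONS), logical(1))
  hasMed <- vapply(cls, function(m) any(m %in% MED_CVD), logical(1))
  prov <- ifelse(hasHist, "history", ifelse(hasMed, "medication", "none"))
  data.frame(cvd = hasHist | hasMed, cvd_provenance = prov,
             stringsAsFactors = FALSE)
}
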