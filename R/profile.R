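#' @keywords internal
#' @import stats
#' @importFrom utils read.csv write.csv capture.output
"_PACKAGE"

## Controlled vocabularies used across the package.
OCSP_LEVELS <- c("TACI", "PACI", "POCI", "LACI", "UNCERTAIN")
ANTIPLATELET_LEVELS <- c("NONE", "ASPIRIN_MONO", "ASPIRIN_PLUS_CLOPIDOGREL")
STRATUM_LEVELS <- c("LOW", "AVERAGE", "ELEVATED")
SICH_DEFINITIONS <- c("NINDS", "ECASS2", "SITSMOST")
ICH_TYPES <- c("NONE", "HI1", "HI2", "PH1", "PH2", "PHr1", "PHr2")

## mmol/L -> mg/dL for glucose (molar mass of glucose, g/mol / 10)
MGDL_PER_MMOL <- 18.016

#' Construct a validated patient profile
#'
#' A patient profile carries the nine pretreatment variables of the SITS
#' SICH risk score plus the OCSP stroke-syndrome category needed for the
#' extended score.  Glucose must carry an explicit unit tag; it is
#' normalized internally to mg/dL (1 mmol/L = 18.016 mg/dL) before the
#' 180 mg/dL threshold is applied.
#'
#' @param age Age in years (non-negative).
#' @param nihss_baseline Baseline NIHSS, integer in \[0, 42\].
#' @param glucose Blood glucose in the unit given by `glucose_unit`.
#' @param glucose_unit `"mgdl"` or `"mmol"`.
#' @param sbp Systolic blood pressure, mm Hg.
#' @param weight Body weight, kg.
#' @param ott_minutes Onset-to-treatment time, minutes.
#' @param hypertension_history Logical; history of hypertension.
#' @param antiplatelet One of `"NONE"`, `"ASPIRIN_MONO"`,
#'   `"ASPIRIN_PLUS_CLOPIDOGREL"`.  Monotherapy and combination therapy
#'   are mutually exclusive states.
#' @param ocsp One of `"TACI"`, `"PACI"`, `"POCI"`, `"LACI"`,
#'   `"UNCERTAIN"`, or `NA` if unknown (allowed only when the extended
#'   score is not requested).
#' @return An object of class `patient_profile`.
#' @examples
#' p <- patient_profile(age = 80, nihss_baseline = 20, glucose = 200,
#'                      glucose_unit = "mgdl", sbp = 150, weight = 100,
#'                      ott_minutes = 185, hypertension_history = TRUE,
#'                      antiplatelet = "ASPIRIN_PLUS_CLOPIDOGREL",
#'                      ocsp = "TACI")
#' compute_sits_score(p)$total  # 12
#' @export
patient_profile <- function(age = NA_real_, nihss_baseline = NA_real_,
                            glucose = NA_real_,
                            glucose_unit = c("mgdl", "mmol"),
                            sbp = NA_real_, weight = NA_real_,
                            ott_minutes = NA_real_,
                            hypertension_history = NA,
                            antiplatelet = NA_character_,
                            ocsp = NA_character_) {
  if (!is.na(glucose)) glucose_unit <- match.arg(glucose_unit)
  else glucose_unit <- NA_character_
  if (!is.na(nihss_baseline) &&
      (nihss_baseline < 0 || nihss_baseline > 42 ||
       nihss_baseline != round(nihss_baseline))) {
    stop("nihss_baseline must be an integer in [0, 42], got ",
         nihss_baseline, call. = FALSE)
  }
  for (nm in c("age", "glucose", "sbp", "weight", "ott_minutes")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) {
      stop(nm, " must be non-negative, got ", v, call. = FALSE)
    }
  }
  if (!is.na(antiplatelet) && !antiplatelet %in% ANTIPLATELET_LEVELS) {
    stop("antiplatelet must be one of ",
         paste(ANTIPLATELET_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (!is.na(ocsp) && !ocsp %in% OCSP_LEVELS) {
    stop("ocsp must be one of ", paste(OCSP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(age = age, nihss_baseline = nihss_baseline,
         glucose = glucose, glucose_unit = glucose_unit,
         sbp = sbp, weight = weight, ott_minutes = ott_minutes,
         hypertension_history = hypertension_history,
         antiplatelet = antiplatelet, ocsp = ocsp),
    class = "patient_profile")
}

## Glucose normalized to mg/dL; NA passes through.
glucose_mgdl <- function(profile) {
  g <- profile$glucose
  if (is.na(g)) return(NA_real_)
  switch(profile$glucose_unit,
         mgdl = g,
         mmol = g * MGDL_PER_MMOL,
         stop("glucose present but glucose_unit missing", call. = FALSE))
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile>\n")
  cat(sprintf("  age %s y, NIHSS %s, glucose %s %s, SBP %s mm Hg\n",
              x$age, x$nihss_baseline, x$glucose,
              ifelse(is.na(x$glucose_unit), "", x$glucose_unit), x$sbp))
  cat(sprintf("  weight %s kg, OTT %s min, HTN %s, antiplatelet %s, OCSP %s\n",
              x$weight, x$ott_minutes, x$hypertension_history,
              x$antiplatelet, x$ocsp))
  invisible(x)
}
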