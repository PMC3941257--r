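## OCSP (Oxfordshire Community Stroke Project) stroke syndromes:
## structured symptom checklist -> category, multi-rater resolution,
## and Cohen's kappa for inter-rater agreement.

#' Construct a structured OCSP symptom checklist
#'
#' The OCSP syndromes are determined clinically (imaging-free) from the
#' maximal pretreatment neurological deficit.  This package takes a
#' pre-structured checklist rather than free text.
#'
#' @param higher_cortical_dysfunction Logical; dysphasia, neglect,
#'   visuospatial disorder, etc.
#' @param homonymous_hemianopia Logical.
#' @param motor_sensory_deficit `"NONE"`, `"PARTIAL"` (limited
#'   face/arm/leg involvement) or `"EXTENSIVE"` (at least two of
#'   face/arm/leg).
#' @param brainstem_cerebellar_signs Logical.
#' @param pure_lacunar_syndrome Logical; pure motor, pure sensory,
#'   sensorimotor stroke or ataxic hemiparesis.  Incompatible with
#'   cortical signs or hemianopia.
#' @return A `symptom_profile` object.
#' @export
symptom_profile <- function(higher_cortical_dysfunction = FALSE,
                            homonymous_hemianopia = FALSE,
                            motor_sensory_deficit = c("NONE", "PARTIAL",
                                                      "EXTENSIVE"),
                            brainstem_cerebellar_signs = FALSE,
                            pure_lacunar_syndrome = FALSE) {
  motor_sensory_deficit <- match.arg(motor_sensory_deficit)
  if (pure_lacunar_syndrome &&
      (higher_cortical_dysfunction || homonymous_hemianopia)) {
    stop("pure lacunar syndrome is incompatible with cortical ",
         "dysfunction or hemianopia", call. = FALSE)
  }
  structure(list(
    higher_cortical_dysfunction = higher_cortical_dysfunction,
    homonymous_hemianopia = homonymous_hemianopia,
    motor_sensory_deficit = motor_sensory_deficit,
    brainstem_cerebellar_signs = brainstem_cerebellar_signs,
    pure_lacunar_syndrome = pure_lacunar_syndrome),
    class = "symptom_profile")
}

#' Classify a symptom checklist into an OCSP category
#'
#' Rules follow the standard OCSP (Bamford) scheme: TACI requires the
#' full triad (higher cortical dysfunction AND homonymous hemianopia
#' AND extensive motor/sensory deficit); brainstem or cerebellar signs
#' — or isolated hemianopia — indicate POCI; a pure lacunar syndrome
#' without cortical signs is LACI; any partial anterior combination
#' (two of the three TACI components, isolated cortical dysfunction,
#' or a partial deficit) is PACI; otherwise UNCERTAIN.
#'
#' @param symptoms A [symptom_profile()].
#' @return One of `"TACI"`, `"PACI"`, `"POCI"`, `"LACI"`, `"UNCERTAIN"`.
#' @export
classify_ocsp <- function(symptoms) {
  stopifnot(inherits(symptoms, "symptom_profile"))
  cortical <- symptoms$higher_cortical_dysfunction
  hemi <- symptoms$homonymous_hemianopia
  deficit <- symptoms$motor_sensory_deficit
  extensive <- deficit == "EXTENSIVE"
  any_deficit <- deficit != "NONE"

  if (cortical && hemi && extensive) return("TACI")
  if (symptoms$brainstem_cerebellar_signs) return("POCI")
  ## isolated homonymous hemianopia is a posterior (PCA) syndrome
  if (hemi && !cortical && !any_deficit) return("POCI")
  if (symptoms$pure_lacunar_syndrome && !cortical && !hemi) return("LACI")
  ## partial anterior: any 2 of the triad, isolated cortical signs,
  ## or a restricted (partial) deficit
  n_triad <- cortical + hemi + extensive
  if (n_triad == 2 || cortical || (hemi && any_deficit) ||
      deficit == "PARTIAL") {
    return("PACI")
  }
  "UNCERTAIN"
}

#' Resolve independent rater classifications
#'
#' Two primary raters; a discrepancy is resolved by a third rater
#' matching either, otherwise the patient is classified UNCERTAIN.
#'
#' @param r1,r2 Primary rater categories.
#' @param r3 Optional adjudicating rater category (`NA` if absent).
#' @return The consensus OCSP category.
#' @export
resolve_raters <- function(r1, r2, r3 = NA_character_) {
  for (r in list(r1, r2)) {
    if (is.na(r) || !r %in% OCSP_LEVELS) {
      stop("at least two valid ratings are required", call. = FALSE)
    }
  }
  if (r1 == r2) return(r1)
  if (!is.na(r3)) {
    if (!r3 %in% OCSP_LEVELS) stop("invalid third rating", call. = FALSE)
    if (r3 == r1) return(r1)
    if (r3 == r2) return(r2)
  }
  "UNCERTAIN"
}

#' Cohen's kappa for inter-rater agreement
#'
#' Unweighted kappa over the five OCSP categories (or any common label
#' set): kappa = (po - pe) / (1 - pe), where po is the observed and pe
#' the chance-expected agreement from the raters' marginal
#' distributions.
#'
#' @param ratings1,ratings2 Equal-length character vectors of
#'   categories, one element per rated item.
#' @param levels Category labels; defaults to the union of observed
#'   labels (OCSP levels when all ratings are OCSP categories).
#' @return A list: `kappa`, `observed_agreement`, `expected_agreement`,
#'   `n_items`, and the confusion `table`.
#' @examples
#' cohen_kappa(c("TACI", "PACI", "TACI"), c("TACI", "PACI", "TACI"))$kappa
#' @export
cohen_kappa <- function(ratings1, ratings2, levels = NULL) {
  n <- length(ratings1)
  if (n == 0 || length(ratings2) != n) {
    stop("rating vectors must be non-empty and of equal length",
         call. = FALSE)
  }
  if (is.null(levels)) {
    obs <- unique(c(ratings1, ratings2))
    levels <- if (all(obs %in% OCSP_LEVELS)) OCSP_LEVELS else sort(obs)
  }
  f1 <- factor(ratings1, levels = levels)
  f2 <- factor(ratings2, levels = levels)
  if (anyNA(f1) || anyNA(f2)) stop("ratings outside the level set",
                                   call. = FALSE)
  tab <- table(f1, f2)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) stop("expected agreement is 1; kappa undefined ",
                    "(degenerate input)", call. = FALSE)
  structure(list(kappa = (po - pe) / (1 - pe),
                 observed_agreement = po, expected_agreement = pe,
                 n_items = n, table = tab),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa = %.3f  (observed %.3f, expected %.3f, n = %d)\n",
    x$kappa, x$observed_agreement, x$expected_agreement, x$n_items))
  print(x$table)
  invisible(x)
}
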