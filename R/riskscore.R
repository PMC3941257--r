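## Risk-score computation: the 12-point SITS SICH score and the 15-point
## OCSP-extended score, plus risk-stratum assignment.

## Component names, in the order they are reported.
SITS_COMPONENTS <- c("antiplatelet", "nihss", "glucose", "age", "sbp",
                     "weight", "ott", "hypertension")

## Resolve one component's points.  `strict` governs missing data:
## strict -> error naming the field; permissive -> 0 points + warning.
component_points <- function(name, value, strict) {
  if (length(value) == 0 || is.na(value)) {
    if (strict) {
      stop("missing required field for component '", name,
           "' (strict mode)", call. = FALSE)
    }
    warning("component '", name, "' missing; scored as absent (0 points)",
            call. = FALSE)
    return(0L)
  }
  switch(name,
    antiplatelet = switch(value, ASPIRIN_PLUS_CLOPIDOGREL = 3L,
                          ASPIRIN_MONO = 2L, NONE = 0L),
    nihss        = if (value >= 13) 2L else if (value >= 7) 1L else 0L,
    glucose      = if (value >= 180) 2L else 0L,
    age          = if (value >= 72) 1L else 0L,
    sbp          = if (value >= 146) 1L else 0L,
    weight       = if (value >= 95) 1L else 0L,
    ott          = if (value >= 180) 1L else 0L,
    hypertension = if (isTRUE(value)) 1L else 0L)
}

#' Compute the SITS SICH risk score
#'
#' Nine weighted pretreatment variables; all cutoffs are ">=" as
#' published: aspirin + clopidogrel 3 points (XOR aspirin monotherapy
#' 2), NIHSS >=13 gives 2 / 7-12 gives 1, glucose >=180 mg/dL 2, age
#' >=72 y 1, SBP >=146 mm Hg 1, weight >=95 kg 1, onset-to-treatment
#' time >=180 min 1, history of hypertension 1.  Total ranges 0-12.
#'
#' @param profile A [patient_profile()].
#' @param strict If `TRUE` (default) a missing component raises an
#'   error naming the field; if `FALSE` a missing binary/categorical
#'   factor scores 0 with a warning.
#' @return A `score_result` list: `total`, named integer vector
#'   `components`, `score_kind = "SITS"`, `poci_zeroed = FALSE`.
#' @seealso [compute_extended_score()], [stratify()]
#' @export
compute_sits_score <- function(profile, strict = TRUE) {
  stopifnot(inherits(profile, "patient_profile"))
  vals <- list(
    antiplatelet = profile$antiplatelet,
    nihss        = profile$nihss_baseline,
    glucose      = glucose_mgdl(profile),
    age          = profile$age,
    sbp          = profile$sbp,
    weight       = profile$weight,
    ott          = profile$ott_minutes,
    hypertension = profile$hypertension_history)
  pts <- vapply(SITS_COMPONENTS,
                function(nm) component_points(nm, vals[[nm]], strict),
                integer(1))
  structure(list(total = sum(pts), components = pts,
                 score_kind = "SITS", poci_zeroed = FALSE),
            class = "score_result")
}

#' Compute the OCSP-extended SICH risk score
#'
#' Adds an OCSP component to the SITS score: TACI contributes
#' `taci_weight` points (default 3, giving a 0-15 range); PACI, LACI
#' and UNCERTAIN contribute 0; a POCI patient is assigned an extended
#' score of zero irrespective of the SITS total.  `taci_weight`
#' reproduces the published weight-exploration design; POCI zeroing
#' applies for every weight.
#'
#' @inheritParams compute_sits_score
#' @param taci_weight Non-negative integer points awarded to TACI.
#' @return A `score_result` with `score_kind = "EXTENDED"` and
#'   `poci_zeroed` flag.
#' @export
compute_extended_score <- function(profile, taci_weight = 3L,
                                   strict = TRUE) {
  stopifnot(inherits(profile, "patient_profile"))
  if (is.na(taci_weight) || taci_weight < 0 ||
      taci_weight != round(taci_weight)) {
    stop("taci_weight must be a non-negative integer", call. = FALSE)
  }
  ocsp <- profile$ocsp
  if (is.na(ocsp)) {
    if (strict) stop("missing required field for component 'ocsp' ",
                     "(strict mode)", call. = FALSE)
    warning("ocsp missing; treated as UNCERTAIN (0 points)",
            call. = FALSE)
    ocsp <- "UNCERTAIN"
  }
  base <- compute_sits_score(profile, strict = strict)
  if (ocsp == "POCI") {
    return(structure(list(total = 0L,
                          components = c(base$components,
                                         ocsp = -base$total),
                          score_kind = "EXTENDED", poci_zeroed = TRUE),
                     class = "score_result"))
  }
  ocsp_pts <- if (ocsp == "TACI") as.integer(taci_weight) else 0L
  structure(list(total = base$total + ocsp_pts,
                 components = c(base$components, ocsp = ocsp_pts),
                 score_kind = "EXTENDED", poci_zeroed = FALSE),
            class = "score_result")
}

#' Assign a risk stratum to a score
#'
#' SITS: 0-2 LOW, 3-5 AVERAGE, >=6 ELEVATED.  Extended: 0-3 LOW, 4-7
#' AVERAGE, >=8 ELEVATED (cutoffs aligned so the strata cover the same
#' clinical range once the 3-point TACI component is added).
#'
#' @param score A `score_result`, or an integer total (then
#'   `score_kind` must be supplied).
#' @param score_kind `"SITS"` or `"EXTENDED"`; ignored when `score` is
#'   a `score_result`.
#' @return Character scalar: `"LOW"`, `"AVERAGE"` or `"ELEVATED"`.
#' @export
stratify <- function(score, score_kind = NULL) {
  if (inherits(score, "score_result")) {
    total <- score$total
    score_kind <- score$score_kind
  } else {
    total <- score
    if (is.null(score_kind)) stop("score_kind required for a bare total",
                                  call. = FALSE)
  }
  score_kind <- match.arg(score_kind, c("SITS", "EXTENDED"))
  if (is.na(total) || total < 0) stop("score total must be >= 0",
                                      call. = FALSE)
  cuts <- if (score_kind == "SITS") c(3, 6) else c(4, 8)
  if (total < cuts[1]) "LOW" else if (total < cuts[2]) "AVERAGE"
  else "ELEVATED"
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<%s score: %d points%s>\n", x$score_kind, x$total,
              if (x$poci_zeroed) " (POCI: zeroed)" else ""))
  print(x$components)
  invisible(x)
}

#' Score every patient in a cohort table
#'
#' Vectorized driver used by the `score` CLI command: appends
#' `sits_score`, `ext_score`, `sits_stratum`, `ext_stratum` columns.
#'
#' @param cohort A data frame in the cohort CSV schema (see
#'   [read_cohort()]).
#' @param taci_weight Passed to [compute_extended_score()].
#' @param strict Missing-data policy, see [compute_sits_score()].
#' @return `cohort` with the four score columns appended.
#' @export
score_cohort <- function(cohort, taci_weight = 3L, strict = TRUE) {
  profiles <- cohort_profiles(cohort)
  sits <- vapply(profiles, function(p)
    compute_sits_score(p, strict = strict)$total, integer(1))
  ext <- vapply(profiles, function(p)
    compute_extended_score(p, taci_weight = taci_weight,
                           strict = strict)$total, integer(1))
  cohort$sits_score <- sits
  cohort$ext_score <- ext
  cohort$sits_stratum <- vapply(sits, stratify, character(1),
                                score_kind = "SITS")
  cohort$ext_stratum <- vapply(ext, stratify, character(1),
                               score_kind = "EXTENDED")
  cohort
}
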