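## SICH adjudication under the NINDS, ECASS II and SITS-MOST
## definitions, from structured follow-up records.

#' Construct an imaging finding
#'
#' @param hours_post_tpa Scan time, hours after thrombolysis (>= 0).
#' @param ich_type Hemorrhage type on the radiology report: `"NONE"`,
#'   `"HI1"`, `"HI2"`, `"PH1"`, `"PH2"` (parenchymal hematoma type 2),
#'   or the remote forms `"PHr1"`, `"PHr2"`.
#' @return An `imaging_finding` list with derived `ich_present`.
#' @export
imaging_finding <- function(hours_post_tpa, ich_type = "NONE") {
  if (is.na(hours_post_tpa) || hours_post_tpa < 0) {
    stop("hours_post_tpa must be >= 0", call. = FALSE)
  }
  ich_type <- match.arg(ich_type, ICH_TYPES)
  structure(list(hours_post_tpa = hours_post_tpa, ich_type = ich_type,
                 ich_present = ich_type != "NONE"),
            class = "imaging_finding")
}

#' Construct a follow-up record
#'
#' Substrate for SICH adjudication: baseline NIHSS, serial NIHSS
#' measurements within 7 days (168 h), death within 7 days, and the
#' post-treatment scans.
#'
#' @param nihss_baseline Baseline NIHSS, integer in \[0, 42\].
#' @param nihss_series Data frame with columns `hours` (0-168) and
#'   `nihss` (0-42), or `NULL`/empty.
#' @param death_within_7d Logical.
#' @param scans List of [imaging_finding()] objects (may be empty).
#' @return A `followup_record`.
#' @export
followup_record <- function(nihss_baseline, nihss_series = NULL,
                            death_within_7d = FALSE, scans = list()) {
  if (is.na(nihss_baseline) || nihss_baseline < 0 ||
      nihss_baseline > 42) {
    stop("nihss_baseline must be in [0, 42]", call. = FALSE)
  }
  if (is.null(nihss_series)) {
    nihss_series <- data.frame(hours = numeric(0), nihss = numeric(0))
  }
  stopifnot(is.data.frame(nihss_series),
            all(c("hours", "nihss") %in% names(nihss_series)))
  if (nrow(nihss_series) > 0) {
    if (any(nihss_series$hours < 0) || any(nihss_series$hours > 168)) {
      stop("NIHSS series times must lie in [0, 168] hours",
           call. = FALSE)
    }
    if (any(nihss_series$nihss < 0) || any(nihss_series$nihss > 42)) {
      stop("NIHSS values must lie in [0, 42]", call. = FALSE)
    }
  }
  ok <- vapply(scans, inherits, logical(1), what = "imaging_finding")
  if (length(scans) && !all(ok)) {
    stop("scans must be imaging_finding objects", call. = FALSE)
  }
  structure(list(nihss_baseline = nihss_baseline,
                 nihss_series = nihss_series[order(nihss_series$hours), ,
                                             drop = FALSE],
                 death_within_7d = isTRUE(death_within_7d),
                 scans = scans),
            class = "followup_record")
}

## ECASS II deterioration clause: >=4 NIHSS points above baseline or
## above the running minimum (baseline and all earlier measurements)
## at any measurement within 7 days.  The running minimum — not the
## global 7-day minimum — is used, so a deterioration always follows
## its reference point.
deterioration_ge4 <- function(record) {
  s <- record$nihss_series
  if (nrow(s) == 0) return(FALSE)
  run_min <- record$nihss_baseline
  for (i in seq_len(nrow(s))) {
    if (s$nihss[i] - run_min >= 4) return(TRUE)
    run_min <- min(run_min, s$nihss[i])
  }
  FALSE
}

#' Adjudicate SICH under the three definitions
#'
#' * **NINDS**: any ICH on any post-treatment scan, together with any
#'   neurological worsening (NIHSS increase >= 1 from baseline) within
#'   36 hours.  Attribution of the worsening to the hemorrhage is
#'   operationalized as co-occurrence.
#' * **ECASS II**: any type of ICH on any post-treatment imaging, and
#'   NIHSS deterioration >= 4 from baseline or from the lowest earlier
#'   value within 7 days, or death within 7 days.
#' * **SITS-MOST**: a local or remote type 2 parenchymal hemorrhage
#'   (PH2/PHr2) on the 22-36 hour scan (boundaries inclusive), plus
#'   the same >= 4-point deterioration or death clause.
#'
#' SITS-MOST positivity implies ECASS II positivity by construction.
#'
#' @param record A [followup_record()].
#' @param strict If `TRUE`, an empty NIHSS series is a missing-data
#'   error; if `FALSE` the NIHSS-based clauses are simply unmet.
#' @return A list `sich_verdict`: logicals `ninds`, `ecass2`,
#'   `sits_most`.
#' @export
adjudicate <- function(record, strict = TRUE) {
  stopifnot(inherits(record, "followup_record"))
  if (length(record$scans) == 0) {
    warning("no post-treatment scans; all verdicts FALSE",
            call. = FALSE)
    return(structure(list(ninds = FALSE, ecass2 = FALSE,
                          sits_most = FALSE), class = "sich_verdict"))
  }
  if (nrow(record$nihss_series) == 0 && strict) {
    stop("empty NIHSS series (strict mode): cannot evaluate ",
         "deterioration clauses", call. = FALSE)
  }
  any_ich <- any(vapply(record$scans, `[[`, logical(1), "ich_present"))
  ph2_window <- any(vapply(record$scans, function(sc) {
    sc$ich_type %in% c("PH2", "PHr2") &&
      sc$hours_post_tpa >= 22 && sc$hours_post_tpa <= 36
  }, logical(1)))

  s <- record$nihss_series
  worsen1_36h <- nrow(s) > 0 &&
    any(s$hours <= 36 & s$nihss >= record$nihss_baseline + 1)
  det4 <- deterioration_ge4(record)
  death <- record$death_within_7d

  structure(list(
    ninds = any_ich && worsen1_36h,
    ecass2 = any_ich && (det4 || death),
    sits_most = ph2_window && (det4 || death)),
    class = "sich_verdict")
}

#' @export
print.sich_verdict <- function(x, ...) {
  cat(sprintf("SICH: NINDS=%s ECASS II=%s SITS-MOST=%s\n",
              x$ninds, x$ecass2, x$sits_most))
  invisible(x)
}

#' Adjudicate a cohort from long-format follow-up data
#'
#' Driver for the `adjudicate` CLI command.  `followup` is a long
#' table with columns `patient_id`, `event_type`
#' (`"nihss"`/`"scan"`/`"death"`), `hours`, `value` (NIHSS points or
#' an ICH-type token).  Baseline NIHSS is taken from the cohort table.
#'
#' @param cohort Cohort data frame with `patient_id` and
#'   `nihss_baseline`.
#' @param followup Long-format follow-up data frame.
#' @param strict Passed to [adjudicate()].
#' @return Data frame: `patient_id`, `ninds`, `ecass2`, `sits_most`.
#' @export
adjudicate_cohort <- function(cohort, followup, strict = TRUE) {
  stopifnot(all(c("patient_id", "nihss_baseline") %in% names(cohort)))
  stopifnot(all(c("patient_id", "event_type", "hours", "value") %in%
                  names(followup)))
  fu_split <- split(followup, factor(followup$patient_id,
                                     levels = unique(cohort$patient_id)))
  empty_fu <- followup[0, , drop = FALSE]
  res <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    fu <- fu_split[[as.character(pid)]]
    if (is.null(fu)) fu <- empty_fu
    nih <- fu[fu$event_type == "nihss", , drop = FALSE]
    sc <- fu[fu$event_type == "scan", , drop = FALSE]
    rec <- followup_record(
      nihss_baseline = cohort$nihss_baseline[i],
      nihss_series = data.frame(hours = as.numeric(nih$hours),
                                nihss = as.numeric(nih$value)),
      death_within_7d = any(fu$event_type == "death"),
      scans = lapply(seq_len(nrow(sc)), function(j)
        imaging_finding(as.numeric(sc$hours[j]),
                        as.character(sc$value[j]))))
    v <- adjudicate(rec, strict = strict)
    data.frame(patient_id = pid, ninds = v$ninds, ecass2 = v$ecass2,
               sits_most = v$sits_most)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
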