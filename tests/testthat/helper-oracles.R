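## Independent oracles and fixture builders shared across test files.
## These deliberately avoid the code paths they check: the AUC and
## DeLong oracles are O(n^2) pair enumerations, kappa is computed
## straight from a confusion matrix.

## Quick profile builder with neutral defaults (scores 0 points).
make_profile <- function(age = 50, nihss = 5, glucose = 100,
                         glucose_unit = "mgdl", sbp = 120,
                         weight = 70, ott = 90, htn = FALSE,
                         antiplatelet = "NONE", ocsp = "PACI") {
  patient_profile(age = age, nihss_baseline = nihss,
                  glucose = glucose, glucose_unit = glucose_unit,
                  sbp = sbp, weight = weight, ott_minutes = ott,
                  hypertension_history = htn,
                  antiplatelet = antiplatelet, ocsp = ocsp)
}

## A profile crossing every SITS threshold (12 points).
make_max_profile <- function(ocsp = "TACI") {
  make_profile(age = 80, nihss = 20, glucose = 200, sbp = 150,
               weight = 100, ott = 185, htn = TRUE,
               antiplatelet = "ASPIRIN_PLUS_CLOPIDOGREL", ocsp = ocsp)
}

## Brute-force AUC: enumerate all case-control pairs, ties count 1/2.
brute_auc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  cases <- scores[y]
  ctrls <- scores[!y]
  tot <- 0
  for (xc in cases) for (xn in ctrls) {
    tot <- tot + (xc > xn) + 0.5 * (xc == xn)
  }
  tot / (length(cases) * length(ctrls))
}

## Brute-force DeLong structural components by explicit double loops.
brute_delong <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  cases <- scores[y]
  ctrls <- scores[!y]
  m <- length(cases)
  n <- length(ctrls)
  psi <- function(x, yv) (x > yv) + 0.5 * (x == yv)
  v10 <- vapply(cases, function(x) mean(psi(x, ctrls)), numeric(1))
  v01 <- vapply(ctrls, function(yv) mean(psi(cases, yv)), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

## Brute-force paired DeLong z for two scores on the same subjects.
brute_delong_z <- function(s1, s2, outcomes) {
  a <- brute_delong(s1, outcomes)
  b <- brute_delong(s2, outcomes)
  s10 <- cov(cbind(a$v10, b$v10))
  s01 <- cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  (b$auc - a$auc) / sqrt(v)
}

## Kappa straight from a confusion matrix of counts.
kappa_from_table <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

## Expand a 2x2 confusion matrix into two rating vectors.
ratings_from_table <- function(m, labels = c("A", "B")) {
  r1 <- character(0)
  r2 <- character(0)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    k <- m[i, j]
    r1 <- c(r1, rep(labels[i], k))
    r2 <- c(r2, rep(labels[j], k))
  }
  list(r1 = r1, r2 = r2)
}

## Enumerate all on/off combinations of the SITS components as
## profiles; returns a list of patient_profile objects.
all_component_profiles <- function(ocsp = "PACI") {
  grid <- expand.grid(
    ap = c("NONE", "ASPIRIN_MONO", "ASPIRIN_PLUS_CLOPIDOGREL"),
    nihss = c(5, 10, 20),         # 0 / 1 / 2 points
    glucose = c(100, 200),        # 0 / 2
    age = c(50, 80), sbp = c(120, 150), weight = c(70, 100),
    ott = c(90, 185), htn = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    make_profile(age = grid$age[i], nihss = grid$nihss[i],
                 glucose = grid$glucose[i], sbp = grid$sbp[i],
                 weight = grid$weight[i], ott = grid$ott[i],
                 htn = grid$htn[i], antiplatelet = grid$ap[i],
                 ocsp = ocsp)
  })
}

## Random follow-up record generator for property sweeps.
random_followup <- function() {
  base <- sample(0:42, 1)
  n_meas <- sample(0:4, 1)
  series <- if (n_meas > 0) {
    data.frame(hours = sort(runif(n_meas, 0, 168)),
               nihss = sample(0:42, n_meas, replace = TRUE))
  } else NULL
  n_scan <- sample(1:3, 1)
  scans <- lapply(seq_len(n_scan), function(i)
    imaging_finding(runif(1, 0, 72),
                    sample(sichscore:::ICH_TYPES, 1)))
  followup_record(base, series, death_within_7d = runif(1) < 0.2,
                  scans = scans)
}
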