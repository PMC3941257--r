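## Evaluation statistics for paired risk scores: univariate logistic
## regression (odds ratio per point), Hosmer-Lemeshow calibration,
## AUC with DeLong / bootstrap confidence intervals, DeLong paired
## comparison of correlated AUCs, reclassification tables and the
## categorical net reclassification improvement (NRI).

#' Univariate logistic regression of outcome on score
#'
#' Maximum-likelihood fit of logit P(event) = intercept + slope * score
#' by iteratively reweighted least squares (IRLS), giving the odds
#' ratio per point increase with a Wald 95% CI.  Convergence: relative
#' change in log-likelihood below `tol` (default 1e-8), at most
#' `max_iter` iterations.
#'
#' @param scores Numeric vector of risk-score values.
#' @param outcomes Logical (or 0/1) event indicator, same length.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A `logistic_fit` list: `intercept`, `slope`,
#'   `odds_ratio_per_point`, `ci95` (on the OR scale), `se_slope`,
#'   `converged`, `n_iter`.
#' @export
fit_univariate_logistic <- function(scores, outcomes, tol = 1e-8,
                                    max_iter = 100L) {
  y <- as.numeric(outcomes)
  x <- as.numeric(scores)
  n <- length(y)
  if (length(x) != n || n == 0) {
    stop("scores and outcomes must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("outcomes must be binary",
                                 call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  X <- cbind(1, x)
  beta <- c(log(mean(y) / (1 - mean(y))), 0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    ll <- sum(y * eta - log1p(exp(eta)))
    w <- p * (1 - p)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    ## weighted least squares step on the working response
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    fisher <- XtW %*% X
    beta_new <- tryCatch(solve(fisher, XtW %*% z),
                         error = function(e)
                           stop("singular information matrix ",
                                "(degenerate scores)", call. = FALSE))
    beta <- unname(drop(beta_new))
    if (is.finite(ll) && abs(ll - ll_old) <
        tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged || abs(beta[2]) > 50) {
    stop("logistic fit did not converge (possible complete separation)",
         call. = FALSE)
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  vc <- solve(t(X * w) %*% X)
  se <- sqrt(diag(vc))
  or <- exp(beta[2])
  ci <- exp(beta[2] + c(-1, 1) * qnorm(0.975) * se[2])
  structure(list(intercept = beta[1], slope = beta[2],
                 odds_ratio_per_point = or, ci95 = ci,
                 se_slope = se[2], se_intercept = se[1],
                 converged = converged, n_iter = iter),
            class = "logistic_fit")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are grouped by quantiles of predicted probability (tied
#' predictions stay in one group); within each group the statistic
#' accumulates (O - E)^2 / (E (1 - E/n_g)), where O and E are observed
#' and expected event counts.  Reference distribution: chi-square with
#' `n_groups - 2` degrees of freedom.
#'
#' @param predicted Predicted event probabilities in \[0, 1\].
#' @param outcomes Binary event indicator.
#' @param n_groups Number of quantile groups (default 10).
#' @return A `calibration_result`: `hl_statistic`, `df`, `p_value`,
#'   and a per-group data frame `groups` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(predicted, outcomes, n_groups = 10L) {
  p <- as.numeric(predicted)
  y <- as.numeric(outcomes)
  n <- length(p)
  stopifnot(length(y) == n)
  if (any(p < 0 | p > 1)) stop("predicted must be probabilities",
                               call. = FALSE)
  if (n < n_groups) stop("need at least n_groups observations",
                         call. = FALSE)
  ## quantile bins; ties kept together by cutting on unique breakpoints
  br <- unique(quantile(p, probs = seq(0, 1, length.out = n_groups + 1),
                        type = 2))
  if (length(br) < 3) {
    ## constant (or near-constant) predictions: single split impossible;
    ## treat all subjects as one comparison of O vs E per forced group
    grp <- cut(seq_len(n), breaks = n_groups, labels = FALSE)
    grp <- grp[rank(p, ties.method = "first")]
  } else {
    grp <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  gl <- sort(unique(grp))
  rows <- lapply(gl, function(g) {
    idx <- grp == g
    data.frame(n = sum(idx), observed = sum(y[idx]),
               expected = sum(p[idx]))
  })
  groups <- do.call(rbind, rows)
  ng <- nrow(groups)
  denom <- groups$expected * (1 - groups$expected / groups$n)
  if (any(denom <= 0)) {
    stop("degenerate group (expected count 0 or n); ",
         "try fewer groups", call. = FALSE)
  }
  stat <- sum((groups$observed - groups$expected)^2 / denom)
  df <- max(ng - 2L, 1L)
  structure(list(hl_statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 groups = groups),
            class = "calibration_result")
}

## DeLong structural components ("placements") via midranks.
## Returns list(auc, v10 [one per case], v01 [one per control]).
delong_placements <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  x_case <- scores[y]
  x_ctrl <- scores[!y]
  m <- length(x_case)
  n <- length(x_ctrl)
  if (m == 0 || n == 0) stop("both outcome classes must be present",
                             call. = FALSE)
  r_all <- rank(c(x_case, x_ctrl), ties.method = "average")
  r_case <- rank(x_case, ties.method = "average")
  r_ctrl <- rank(x_ctrl, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_case) / n            # per case
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m    # per control
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with a DeLong or bootstrap confidence interval
#'
#' The AUC equals the Mann-Whitney probability that a randomly chosen
#' event outranks a randomly chosen nonevent, ties counted one half.
#' The DeLong variance uses the structural components (midrank
#' formulation); the bootstrap CI is the percentile interval over
#' simple case-resampled replicates.
#'
#' @param scores Numeric score vector.
#' @param outcomes Binary event indicator.
#' @param method `"DELONG"` (default) or `"BOOTSTRAP"`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (required for `"BOOTSTRAP"`).
#' @return An `auc_result`: `auc`, `variance`, `ci95`, `ci_method`,
#'   and `n_boot` when bootstrapped.
#' @export
auc_with_ci <- function(scores, outcomes, method = c("DELONG",
                                                     "BOOTSTRAP"),
                        n_boot = 1000L, seed = NULL) {
  method <- match.arg(method)
  pl <- delong_placements(scores, outcomes)
  var_d <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  if (method == "DELONG") {
    half <- qnorm(0.975) * sqrt(var_d)
    ci <- pmin(pmax(pl$auc + c(-1, 1) * half, 0), 1)
    return(structure(list(auc = pl$auc, variance = var_d, ci95 = ci,
                          ci_method = "DELONG", n_boot = NA_integer_),
                     class = "auc_result"))
  }
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- as.logical(outcomes)
  n <- length(y)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (all(y[idx]) || !any(y[idx])) return(NA_real_)
    delong_placements(scores[idx], y[idx])$auc
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  ci <- unname(quantile(reps, c(0.025, 0.975), type = 7))
  structure(list(auc = pl$auc, variance = stats::var(reps), ci95 = ci,
                 ci_method = "BOOTSTRAP", n_boot = length(reps)),
            class = "auc_result")
}

#' DeLong test comparing two correlated AUCs
#'
#' Both scores are measured on the same subjects, so the AUC estimates
#' are correlated; the paired z statistic uses the DeLong
#' variance-covariance of the structural components:
#' z = (auc2 - auc1) / sqrt(v1 + v2 - 2 cov), two-sided normal p.
#'
#' @param scores1,scores2 Score vectors on the same subjects.
#' @param outcomes Binary event indicator.
#' @return An `auc_comparison`: `auc1`, `auc2`, `difference`
#'   (auc2 - auc1), `z`, `p_value`, `var_diff`.
#' @export
compare_auc_delong <- function(scores1, scores2, outcomes) {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(outcomes))
  p1 <- delong_placements(scores1, outcomes)
  p2 <- delong_placements(scores2, outcomes)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / p1$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / p1$n
  diff <- p2$auc - p1$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(diff) > 1e-12) {
      warning("zero DeLong variance with nonzero AUC difference",
              call. = FALSE)
    } else {
      warning("identical rankings: z set to 0, p to 1", call. = FALSE)
    }
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc1 = p1$auc, auc2 = p2$auc, difference = diff,
                 var_diff = var_diff, z = z, p_value = p),
            class = "auc_comparison")
}

#' Cross-tabulate risk reclassification by event status
#'
#' Builds the pair of 3x3 tables (events and nonevents separately)
#' counting moves between risk strata of the old and new score; strata
#' are ordered LOW < AVERAGE < ELEVATED.
#'
#' @param old_cat,new_cat Character vectors of stratum labels.
#' @param outcomes Binary event indicator.
#' @return A `reclassification_table`: integer matrices `events` and
#'   `nonevents` (rows = old stratum, cols = new stratum).
#' @export
reclassification <- function(old_cat, new_cat, outcomes) {
  n <- length(old_cat)
  stopifnot(length(new_cat) == n, length(outcomes) == n)
  fo <- factor(old_cat, levels = STRATUM_LEVELS)
  fn <- factor(new_cat, levels = STRATUM_LEVELS)
  if (anyNA(fo) || anyNA(fn)) stop("invalid stratum label",
                                   call. = FALSE)
  y <- as.logical(outcomes)
  ev <- table(fo[y], fn[y])
  ne <- table(fo[!y], fn[!y])
  structure(list(events = unclass(ev), nonevents = unclass(ne)),
            class = "reclassification_table")
}

#' Categorical net reclassification improvement
#'
#' NRI = (P(up | event) - P(down | event)) -
#'       (P(up | nonevent) - P(down | nonevent)), where "up"/"down"
#' are moves to a higher/lower stratum under LOW < AVERAGE < ELEVATED
#' (a multi-step move counts once).  The significance test is the
#' standard asymptotic z for the categorical NRI:
#' z = NRI / sqrt((up_e + down_e)/n_e + (up_ne + down_ne)/n_ne) with
#' the up/down terms as proportions.
#'
#' @param table A `reclassification_table` from [reclassification()].
#' @return An `nri_result`: `nri`, the four movement proportions,
#'   `z`, `p_value`, `n_events`, `n_nonevents`.
#' @export
nri <- function(table) {
  stopifnot(inherits(table, "reclassification_table"))
  up_down <- function(m) {
    c(up = sum(m[upper.tri(m)]), down = sum(m[lower.tri(m)]),
      n = sum(m))
  }
  e <- up_down(table$events)
  ne <- up_down(table$nonevents)
  if (e["n"] == 0 || ne["n"] == 0) {
    stop("need at least one event and one nonevent", call. = FALSE)
  }
  pe_up <- e[["up"]] / e[["n"]]
  pe_dn <- e[["down"]] / e[["n"]]
  pn_up <- ne[["up"]] / ne[["n"]]
  pn_dn <- ne[["down"]] / ne[["n"]]
  nri_val <- (pe_up - pe_dn) - (pn_up - pn_dn)
  v <- (pe_up + pe_dn) / e[["n"]] + (pn_up + pn_dn) / ne[["n"]]
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- nri_val / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(nri = nri_val, event_up = pe_up, event_down = pe_dn,
                 nonevent_up = pn_up, nonevent_down = pn_dn,
                 z = z, p_value = p,
                 n_events = e[["n"]], n_nonevents = ne[["n"]]),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI = %.3f (%.1f%%), z = %.3f, p = %.3f\n",
              x$nri, 100 * x$nri, x$z, x$p_value))
  cat(sprintf("  events:    %.3f up, %.3f down (n = %d)\n",
              x$event_up, x$event_down, x$n_events))
  cat(sprintf("  nonevents: %.3f up, %.3f down (n = %d)\n",
              x$nonevent_up, x$nonevent_down, x$n_nonevents))
  invisible(x)
}

#' Paired evaluation of the SITS and extended scores
#'
#' Assembles, for one SICH definition, the full comparison: per-point
#' logistic odds ratios, Hosmer-Lemeshow calibration of each fit, AUCs
#' with confidence intervals, the DeLong paired test, the
#' reclassification tables and the NRI.
#'
#' @param scored Data frame with columns `sits_score`, `ext_score`,
#'   `sits_stratum`, `ext_stratum` (from [score_cohort()]).
#' @param verdicts Data frame with logical columns `ninds`, `ecass2`,
#'   `sits_most` (from [adjudicate_cohort()] or
#'   [simulate_outcomes()]), row-aligned with `scored`.
#' @param definition `"NINDS"`, `"ECASS2"` or `"SITSMOST"`.
#' @param ci_method CI method for the AUCs (`"DELONG"` or
#'   `"BOOTSTRAP"`).
#' @param n_boot,seed Bootstrap controls, see [auc_with_ci()].
#' @param hl_groups Hosmer-Lemeshow group count.
#' @return A `comparison_report` list with elements `definition`, `n`,
#'   `n_events`, `fit_sits`, `fit_ext`, `hl_sits`, `hl_ext`,
#'   `auc_sits`, `auc_ext`, `delong`, `reclass`, `nri`.
#' @export
evaluate_pair <- function(scored, verdicts,
                          definition = c("NINDS", "ECASS2", "SITSMOST"),
                          ci_method = c("DELONG", "BOOTSTRAP"),
                          n_boot = 1000L, seed = NULL,
                          hl_groups = 10L) {
  definition <- match.arg(definition)
  ci_method <- match.arg(ci_method)
  stopifnot(nrow(scored) == nrow(verdicts))
  col <- switch(definition, NINDS = "ninds", ECASS2 = "ecass2",
                SITSMOST = "sits_most")
  y <- as.logical(verdicts[[col]])

  fit_s <- fit_univariate_logistic(scored$sits_score, y)
  fit_e <- fit_univariate_logistic(scored$ext_score, y)
  pred_s <- plogis(fit_s$intercept + fit_s$slope * scored$sits_score)
  pred_e <- plogis(fit_e$intercept + fit_e$slope * scored$ext_score)
  hl_s <- hosmer_lemeshow(pred_s, y, n_groups = hl_groups)
  hl_e <- hosmer_lemeshow(pred_e, y, n_groups = hl_groups)
  auc_s <- auc_with_ci(scored$sits_score, y, method = ci_method,
                       n_boot = n_boot, seed = seed)
  auc_e <- auc_with_ci(scored$ext_score, y, method = ci_method,
                       n_boot = n_boot,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  dl <- compare_auc_delong(scored$sits_score, scored$ext_score, y)
  rc <- reclassification(scored$sits_stratum, scored$ext_stratum, y)
  structure(list(definition = definition, n = length(y),
                 n_events = sum(y),
                 fit_sits = fit_s, fit_ext = fit_e,
                 hl_sits = hl_s, hl_ext = hl_e,
                 auc_sits = auc_s, auc_ext = auc_e,
                 delong = dl, reclass = rc, nri = nri(rc)),
            class = "comparison_report")
}
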