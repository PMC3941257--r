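test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  ## (events|score=1, nonevents|1, events|0, nonevents|0) = (10,40,5,45)
  scores <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(TRUE, 10), rep(FALSE, 40), rep(TRUE, 5), rep(FALSE, 45))
  fit <- fit_univariate_logistic(scores, y)
  expect_equal(fit$odds_ratio_per_point, (10 * 45) / (40 * 5),
               tolerance = 1e-6)
  expect_equal(fit$odds_ratio_per_point, exp(fit$slope))
  expect_true(fit$converged)
  expect_true(fit$ci95[1] <= fit$odds_ratio_per_point &&
                fit$odds_ratio_per_point <= fit$ci95[2])
})

test_that("logistic fit agrees with a null and a known-slope truth", {
  set.seed(31)
  n <- 2000
  s <- sample(0:12, n, replace = TRUE)
  ## null slope
  y0 <- runif(n) < 0.2
  f0 <- fit_univariate_logistic(s, y0)
  expect_lt(abs(f0$slope), 3 * f0$se_slope)
  ## known slope 0.30
  y1 <- runif(n) < plogis(-3 + 0.30 * s)
  f1 <- fit_univariate_logistic(s, y1)
  expect_lt(abs(f1$slope - 0.30), 3 * f1$se_slope)
})

test_that("logistic fit input validation and separation", {
  expect_error(fit_univariate_logistic(1:5, c(1, 1, 1, 1, 1)),
               "both outcome classes")
  expect_error(fit_univariate_logistic(1:4, c(0, 1, 1)), "equal length")
  ## complete separation
  expect_error(
    fit_univariate_logistic(c(1, 2, 3, 10, 11, 12),
                            c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
    "converge|separation")
})

test_that("Hosmer-Lemeshow matches the direct group-sum formula", {
  ## fixed 20-subject toy vector, 4 groups, hand-evaluable
  set.seed(5)
  p <- rep(c(0.1, 0.3, 0.5, 0.8), each = 5)
  y <- c(1, 0, 0, 0, 0,  0, 1, 1, 0, 0,  1, 1, 0, 1, 0,  1, 1, 1, 1, 0)
  r <- hosmer_lemeshow(p, y, n_groups = 4)
  ## direct evaluation: groups are the four distinct probabilities
  direct <- 0
  for (pp in c(0.1, 0.3, 0.5, 0.8)) {
    idx <- p == pp
    O <- sum(y[idx]); E <- sum(p[idx]); ng <- sum(idx)
    direct <- direct + (O - E)^2 / (E * (1 - E / ng))
  }
  expect_equal(r$hl_statistic, direct)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, pchisq(direct, 2, lower.tail = FALSE))
})

test_that("Hosmer-Lemeshow df, permutation invariance, degenerate input", {
  set.seed(6)
  p <- runif(500, 0.05, 0.95)
  y <- runif(500) < p
  r <- hosmer_lemeshow(p, y, n_groups = 10)
  expect_equal(r$df, 8L)
  expect_equal(sum(r$groups$n), 500)
  ## permutation invariance
  perm <- sample(500)
  expect_equal(hosmer_lemeshow(p[perm], y[perm])$hl_statistic,
               r$hl_statistic)
  ## constant predictions matching observed rate -> statistic 0
  y2 <- rep(c(TRUE, FALSE), 50)
  r2 <- hosmer_lemeshow(rep(0.5, 100), y2, n_groups = 2)
  expect_equal(r2$hl_statistic, 0)
  expect_error(hosmer_lemeshow(rep(0, 100), rep(0, 100)), "degenerate")
})

test_that("AUC equals brute-force pair enumeration (worked examples)", {
  expect_equal(auc_with_ci(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(auc_with_ci(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(auc_with_ci(c(1, 1, 2), c(0, 1, 1))$auc, 0.75)
})

test_that("property sweep: midrank AUC = brute force for all n <= 12", {
  set.seed(77)
  for (k in 1:200) {
    n <- sample(4:12, 1)
    scores <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)   # both classes present
    expect_equal(auc_with_ci(scores, y)$auc, brute_auc(scores, y))
  }
})

test_that("DeLong variance and comparison match the brute-force oracle", {
  set.seed(88)
  for (k in 1:50) {
    n <- sample(6:12, 1)
    s1 <- sample(1:5, n, replace = TRUE)
    s2 <- sample(1:5, n, replace = TRUE)
    y <- c(TRUE, TRUE, FALSE, FALSE, runif(n - 4) < 0.5)
    bd <- brute_delong(s1, y)
    r <- auc_with_ci(s1, y, method = "DELONG")
    expect_equal(r$variance,
                 var(bd$v10) / bd$m + var(bd$v01) / bd$n)
    cmp <- compare_auc_delong(s1, s2, y)
    if (cmp$var_diff > 1e-12) {
      expect_equal(cmp$z, brute_delong_z(s1, s2, y), tolerance = 1e-10)
    }
    expect_equal(cmp$difference, brute_auc(s2, y) - brute_auc(s1, y))
  }
})

test_that("DeLong comparison edge cases", {
  s <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 0, 1, 0, 1, 1)
  expect_warning(cmp <- compare_auc_delong(s, s, y), "identical")
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  ## strictly monotone transform leaves the AUC unchanged
  cmp2 <- suppressWarnings(compare_auc_delong(s, exp(s), y))
  expect_equal(cmp2$difference, 0)
})

test_that("bootstrap CI is seeded, percentile, and close to DeLong", {
  set.seed(99)
  n <- 400
  s <- sample(0:15, n, replace = TRUE)
  y <- runif(n) < plogis(-3 + 0.25 * s)
  b1 <- auc_with_ci(s, y, method = "BOOTSTRAP", n_boot = 300, seed = 4)
  b2 <- auc_with_ci(s, y, method = "BOOTSTRAP", n_boot = 300, seed = 4)
  expect_identical(b1$ci95, b2$ci95)
  d <- auc_with_ci(s, y, method = "DELONG")
  expect_equal(b1$auc, d$auc)  # point estimate never resampled
  ## bootstrap variance close to DeLong variance (MC tolerance)
  expect_lt(abs(b1$variance - d$variance) / d$variance, 0.5)
})

test_that("reclassification tables and NRI fixtures", {
  old <- c("LOW", "LOW", "AVERAGE", "AVERAGE", "ELEVATED", "ELEVATED")
  new <- c("LOW", "AVERAGE", "LOW", "AVERAGE", "AVERAGE", "ELEVATED")
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  rt <- reclassification(old, new, y)
  expect_equal(sum(rt$events), 3)
  expect_equal(sum(rt$nonevents), 3)
  expect_equal(rt$events["LOW", "AVERAGE"], 1)
  expect_equal(rt$events["ELEVATED", "AVERAGE"], 1)
  expect_equal(rt$nonevents["AVERAGE", "LOW"], 1)
  ## row sums of events matrix = events per old stratum (2, 0, 1)
  expect_equal(unname(rowSums(rt$events)), c(2, 0, 1))
  ## identity reclassification is diagonal
  rt0 <- reclassification(old, old, y)
  expect_true(all(rt0$events[upper.tri(rt0$events)] == 0))
  expect_true(all(rt0$events[lower.tri(rt0$events)] == 0))
  expect_equal(nri(rt0)$nri, 0)
})

test_that("NRI hand fixture: 0.2 exactly, and the extremes", {
  ## events n=10: 2 up, 1 down; nonevents n=30: 3 up, 6 down
  ev <- matrix(c(7, 1, 0,  2, 0, 0,  0, 0, 0), 3,
               dimnames = list(c("LOW", "AVERAGE", "ELEVATED"),
                               c("LOW", "AVERAGE", "ELEVATED")))
  ne <- matrix(c(15, 6, 0,  3, 6, 0,  0, 0, 0), 3,
               dimnames = dimnames(ev))
  tab <- structure(list(events = ev, nonevents = ne),
                   class = "reclassification_table")
  r <- nri(tab)
  expect_equal(r$nri, 0.2)
  expect_equal(r$event_up, 0.2)
  expect_equal(r$nonevent_down, 0.2)
  ## z matches the asymptotic formula
  expect_equal(r$z, 0.2 / sqrt((0.2 + 0.1) / 10 + (0.1 + 0.2) / 30))

  ## all events up, all nonevents down -> NRI = 2
  ev2 <- matrix(0, 3, 3, dimnames = dimnames(ev)); ev2[1, 3] <- 5
  ne2 <- matrix(0, 3, 3, dimnames = dimnames(ev)); ne2[3, 1] <- 7
  tab2 <- structure(list(events = ev2, nonevents = ne2),
                    class = "reclassification_table")
  expect_equal(nri(tab2)$nri, 2)
})

test_that("NRI from a table equals NRI from raw category vectors", {
  set.seed(123)
  lv <- c("LOW", "AVERAGE", "ELEVATED")
  for (k in 1:20) {
    n <- 120
    old <- sample(lv, n, replace = TRUE)
    new <- sample(lv, n, replace = TRUE)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.25)
    r <- nri(reclassification(old, new, y))
    oi <- match(old, lv); ni <- match(new, lv)
    direct <- (mean(ni[y] > oi[y]) - mean(ni[y] < oi[y])) -
      (mean(ni[!y] > oi[!y]) - mean(ni[!y] < oi[!y]))
    expect_equal(r$nri, direct)
  }
})

test_that("evaluate_pair assembles a deterministic report", {
  spec <- cohort_spec(n = 400, seed = 17)
  scored <- score_cohort(generate_cohort(spec))
  sim <- simulate_outcomes(scored, spec, "ECASS2")
  r1 <- evaluate_pair(scored, sim$verdicts, "ECASS2", seed = 3)
  ## rerun from the same inputs: identical values
  r2 <- evaluate_pair(scored, sim$verdicts, "ECASS2", seed = 3)
  expect_equal(r1$auc_ext$auc, r2$auc_ext$auc)
  expect_equal(r1$nri$nri, r2$nri$nri)
  expect_equal(r1$n_events, sum(sim$verdicts$ecass2))
  ## identical scores (degenerate comparison): difference 0, NRI 0
  scored0 <- scored
  scored0$ext_score <- scored0$sits_score
  scored0$ext_stratum <- scored0$sits_stratum
  ## note: ext strata cutpoints differ, so reuse SITS strata for both
  r0 <- suppressWarnings(
    evaluate_pair(scored0, sim$verdicts, "ECASS2"))
  expect_equal(r0$delong$difference, 0)
  expect_equal(r0$nri$nri, 0)
})
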