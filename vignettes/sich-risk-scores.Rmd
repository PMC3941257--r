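---
title: "Risk scoring and evaluation methodology for post-thrombolysis SICH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk scoring and evaluation methodology for post-thrombolysis SICH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sichscore)
```

## The clinical problem

Intravenous thrombolysis with tPA for acute ischemic stroke carries a
risk of symptomatic intracerebral hemorrhage (SICH).  Point-based risk
scores let clinicians quantify that risk before treatment from
bedside variables alone.  `sichscore` implements two such scores and
the full statistical machinery for comparing them:

* the **SITS SICH risk score** — nine weighted pretreatment variables,
  0–12 points;
* an **OCSP-extended score** — the SITS score plus a stroke-syndrome
  component from the Oxfordshire Community Stroke Project (OCSP)
  classification: a total anterior circulation infarct (TACI) adds 3
  points (0–15 total), while a posterior circulation infarct (POCI)
  sets the whole score to zero, reflecting the very low hemorrhage
  risk of posterior strokes.

The OCSP classification is determined purely clinically (no imaging),
which is exactly why it is attractive as a score component in
emergency settings.

## The scores

All cutoffs are "greater than or equal", applied after normalizing
glucose to mg/dL (1 mmol/L = 18.016 mg/dL):

| Component | Points |
|---|---|
| Aspirin + clopidogrel (XOR aspirin monotherapy) | 3 (XOR 2) |
| NIHSS ≥ 13 / 7–12 | 2 / 1 |
| Glucose ≥ 180 mg/dL | 2 |
| Age ≥ 72 y; SBP ≥ 146 mm Hg; weight ≥ 95 kg; OTT ≥ 180 min; hypertension history | 1 each |
| TACI (extended score only) | 3 |

The antiplatelet component is an enum — monotherapy and combination
therapy are mutually exclusive states, so 3 and 2 points can never
add.  Risk strata: SITS 0–2 / 3–5 / ≥6, extended 0–3 / 4–7 / ≥8
(low / average / elevated); the extended cutpoints are shifted by the
3-point TACI weight so the strata stay aligned.

Design choices where the design was genuinely open:

* **UNCERTAIN OCSP** contributes 0 points and is *not* zeroed —
  points attach only to TACI and zeroing only to POCI, and patients
  with undetermined syndromes remain analyzable.
* **`taci_weight`** is a parameter (default 3) so the weight
  exploration that motivated the published 3-point choice can be
  re-run; POCI zeroing is kept for every weight, because zeroing is a
  biological design principle (posterior strokes rarely bleed), not a
  tunable.
* **Missing data**: strict mode (default) raises an error naming the
  missing field; permissive mode scores a missing factor as absent
  with a warning.  No missingness policy is part of the scores
  themselves.

## SICH definitions

`adjudicate()` evaluates three nested-in-spirit definitions from a
structured follow-up record (serial NIHSS, scans with ICH type, death
within 7 days):

* **NINDS** — any ICH plus any NIHSS worsening (≥1 from baseline)
  within 36 h.  "Attributed to ICH" is operationalized as
  co-occurrence; no causality algorithm is published.
* **ECASS II** — any ICH plus deterioration ≥4 from baseline *or from
  the lowest earlier value* within 7 days, or death within 7 days.
* **SITS-MOST** — a local or remote type-2 parenchymal hemorrhage
  (PH2/PHr2) on the 22–36 h scan (boundaries inclusive) plus the same
  ≥4/death clause.  Its death window is mirrored from ECASS II (7
  days), which the source definitions leave unstated.

The "lowest value" reference is the *running* minimum up to each
measurement, not the global 7-day minimum: a deterioration must
follow its reference point.  One consequence worth knowing: raising a
mid-series NIHSS value can *erase* the reference dip for a later
deterioration, so "worsening a value never flips a verdict to false"
is not a theorem under this semantics.  The property tests therefore
check the true monotone statements — appending a measurement never
un-triggers a verdict, and raising a value never un-triggers the
baseline-referenced NINDS clause.  SITS-MOST positivity implies
ECASS II positivity by construction (PH2 in-window is "any ICH"; the
deterioration clause is identical); this is verified by a randomized
sweep.

## Evaluation statistics

All of these are implemented in the package rather than delegated,
since they are the analytical substance being validated; each is
tested against an independent brute-force oracle.

* **Logistic regression** (odds ratio per score point): IRLS with
  relative log-likelihood tolerance 1e-8, max 100 iterations; Wald
  95% CI.  Complete separation raises an explicit error.
* **Hosmer–Lemeshow**: quantile groups (default 10) with tied
  predictions kept together; statistic
  $\sum_g (O_g-E_g)^2 / (E_g(1-E_g/n_g))$, df = groups − 2.
* **AUC**: Mann–Whitney with ties counted ½.  Variance by the DeLong
  structural components (midrank formulation); bootstrap CIs are
  percentile intervals over simple case resampling, 1000 replicates
  by default, always seeded.  The percentile flavor is a choice — the
  source analysis does not state which bootstrap CI it used.
* **Paired AUC comparison**: DeLong z with the component covariance;
  identical rankings give z = 0, p = 1 with a warning.
* **Reclassification / NRI**: 3×3 cross-tabulations by event status,
  categorical NRI with LOW < AVERAGE < ELEVATED (multi-step moves
  count once), and the standard asymptotic z test
  $z = \mathrm{NRI}\big/\sqrt{(u_e+d_e)/n_e + (u_n+d_n)/n_n}$ —
  the companion test of the cited NRI formulation, since no test is
  named in the source analysis.

## The synthetic cohort generator

No patient-level data accompany the source study, so
`generate_cohort()` emulates its published cohort *marginals*: age
N(67, 12), weight N(65, 13) kg, SBP N(161, 30) mm Hg (all truncated
at zero), glucose N(8.49, 3.72) mmol/L, NIHSS and OTT from
discretized gamma distributions quantile-matched to median 13 (IQR
8–20) and 125 (100–155) min, OCSP drawn from the published category
counts (207/162/48/111/20 of 548 — the printed percentages sum to
100.1%, so the probability vector is normalized), hypertension 74.1%,
antiplatelet use 23.5% split 80/20 monotherapy vs combination (only
the total is published; the split is configurable).

Covariates are drawn **independently** — only marginals are
published.  This is the generator's main departure from real data:
true cohorts correlate NIHSS with TACI, glucose with diabetes, and so
on, so a green calibration test establishes marginal fidelity and
pipeline correctness, not joint realism.  NIHSS is truncated at 41
rather than 42 so a 1-point worsening always remains representable in
simulated follow-up.

Outcomes follow logit P(SICH) = α + β·(extended score) with β =
log(1.30) by default — the per-point odds-ratio scale of the
published evaluation — and α solved by root-finding so the expected
marginal rate matches the definition-specific target (7.3% NINDS,
5.3% ECASS II, 3.5% SITS-MOST).  Follow-up records are then
*constructed* so that `adjudicate()` reproduces the simulated label
exactly under the requested definition (events built for SITS-MOST
are also ECASS II positive, respecting the nesting); this
constructive round trip is what makes the whole pipeline testable end
to end.

## Numerical notes

* Scores are exact integer arithmetic; the only unit conversion is
  glucose (× 18.016).
* The gamma quantile matching uses Nelder–Mead least squares on the
  log-parameter scale; any distribution meeting the three quantiles
  would be acceptable.
* `hosmer_lemeshow()` falls back to rank-forced groups when
  predictions are constant, and refuses degenerate groups (expected
  0 or n).
* All stochastic entry points take or require a seed; a fixed seed
  reproduces every table bit-for-bit on the same platform.

## Known limitations

* The published cohort's headline numbers (AUC 0.704 vs 0.624, NRI
  22.3%/21.2%/24.5%, κ = 0.583) cannot be reproduced without the
  registry data; the package reproduces the *methods*, verified on
  synthetic cohorts and worked fixtures.
* Inter-rater κ is computed from supplied rating vectors only; the
  original raters' item-level data are unavailable.
* The OCSP classifier expects a structured checklist; free-text
  chart parsing is out of scope, as is imaging-based territory
  assignment.
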