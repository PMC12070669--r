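---
title: "Three-marker panel rules for endoscopic remission: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-marker panel rules for endoscopic remission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtriad)
```

## The problem

Endoscopy is the reference standard for judging whether Crohn's disease is in
remission, but it is invasive, costly, and — when the small bowel is involved —
requires balloon-assisted enteroscopy. Three non-invasive inflammation markers
are in routine use as surrogates: serum leucine-rich alpha-2 glycoprotein
(LRG, µg/mL), serum C-reactive protein (CRP, mg/dL) and fecal calprotectin
(Fcal, µg/g). Individually each is only moderately accurate. This package
implements and validates *combination rules* over the three markers for
classifying patients as being in endoscopic remission, defined as a modified
Simple Endoscopic Score for Crohn's Disease (mSES-CD; three items scored 0–3
in six bowel segments, total 0–54) of **0 to 2**.

Two conventions hold everywhere in the package and are worth stating once:

* **remission is the positive class** of every diagnostic rule (sensitivity is
  a proportion of the remission patients), and
* **low marker values point toward remission**, so a marker is "negative"
  when its value is at or below its cutoff and informative AUCs are above 0.5
  without any manual sign flipping.

## From continuous markers to rules

Each marker is dichotomized at a cutoff chosen by the **Youden index**
(`youden_cutoff()`): the empirical ROC curve (`empirical_roc()`) is scanned
over the observed unique marker values and the threshold maximizing
J = sensitivity + specificity − 1 is selected, ties broken toward the smallest
cutoff. Candidate cutoffs are restricted to observed values because that is
what an empirical Youden scan can identify; a value exactly at the cutoff is
classified negative (remission-side). The packaged default cutoffs
(`cutoff_set()`: LRG 13.2 µg/mL, CRP 0.15 mg/dL, Fcal 180 µg/g) are the ones
fitted in the source cohort.

The combination rules (`apply_rule()`) are:

* **two_of_three** — remission iff at least 2 of the 3 markers are negative.
  Over three binary markers this is equivalent to "active iff at least 2
  positive", so there is no indeterminate middle.
* **all_three** — remission iff all three are negative (maximally specific).
* **crp_lrg / crp_fcal / fcal_lrg** — remission iff both named markers are
  negative.
* **two_step** — a sequential triage (`classify_two_step()`): classify on the
  two serum markers when they agree; only for discordant serum results is
  Fcal measured, and its status decides. The Fcal measurement is accessed
  through a lazy provider contract, so the fraction of stool tests actually
  avoided is an observable quantity (`fcal_sparing_rate()`), not an
  assumption. A discordant patient whose Fcal cannot be obtained is reported
  `indeterminate`, never silently classified.

A short equivalence argument — verified exhaustively over the 8 status
combinations in the test suite — shows the two-step decision always equals the
two-of-three majority decision: concordant serum statuses already constitute
two votes, and under serum discordance the Fcal vote is the tiebreaker. The
two rules therefore share accuracy exactly; they differ only in how many Fcal
measurements they consume.

Rule performance is summarized (`summarize_confusion()`) as sensitivity,
specificity, PPV, NPV and accuracy with binomial confidence intervals, plus
the AUC of the binary rule, which for a dichotomous classifier is exactly the
balanced accuracy (sens + spec)/2. Two CI methods are provided because
published tables mix them: the Wald interval (which degenerates to 100–100 for
perfect cells) and the exact **Clopper–Pearson** interval, whose all-success
lower bound is (α/2)^(1/n) — e.g. 0.968 for 114/114 and 0.946 for 66/66.
Clopper–Pearson is the default. The AUC interval is a Wald interval on the
balanced-accuracy scale and is tagged approximate. Metrics with zero
denominators are reported `undefined` rather than coerced to 0 or 1.

## Auditing published accuracy tables

When a table prints five proportions to one decimal over known class sizes
(here 116 remission / 114 active), the integer confusion matrix behind each
row is recoverable: `reconstruct_confusion()` inverts printed sensitivity and
specificity, and `consistency_audit()` recomputes every other cell, rounding
**half away from zero** (the display convention that reproduces the bundled
tables; base R's `round()` rounds half to even and does not). The audit also
runs an exhaustive search over all 117 × 115 integer (TP, TN) pairs, so a row
that *no* matrix can explain is flagged as internally inconsistent rather than
silently "corrected". Of the bundled rows, three apparent-performance rows are
inconsistent in this sense, and one cross-validated row prints an AUC one
rounding step away from the value implied by its own counts (0.785 vs 0.784 —
consistent with averaging the already-rounded percentages). These findings are
annotated in the fixture (`printed_tables()`) and asserted by the tests; the
package deliberately reports them instead of reproducing them.

## Cross-validation

`cv_evaluate()` implements stratified k-fold cross-validation for threshold
rules. Two details are interpretations, exposed as explicit knobs, because the
procedure being emulated does not fully specify them:

* **Cutoffs are refit on the training folds** (per-marker Youden) and applied
  to the held-out fold; without refitting, cross-validation of a fixed
  threshold rule is vacuous — indeed with `refit = FALSE` the pooled result
  provably equals the apparent one, which the tests use as a degenerate-case
  oracle.
* **"Diagnostic ability" for selecting k** (`select_k()`, k in 2..10) is the
  pooled AUC, configurable to accuracy. Held-out decisions from all folds are
  pooled into a single confusion matrix, so every patient is counted exactly
  once. Selecting k by maximizing performance is optimistically biased; the
  report says so and keeps all nine candidate values visible.

`compare_rules()` scores each rule's pooled held-out decisions against a
reference rule with the **DeLong test** applied to the binary prediction
scores — an approximation chosen because the compared quantities are pooled
binary calls, not continuous scores. The DeLong machinery itself
(`delong_test()`) is the standard placement-value construction and is verified
in the tests against both a stratified bootstrap oracle and an independent
implementation. Fold assignment is stratified by the truth label (per-stratum
fold sizes differ by at most one, with the remainder rotated across strata so
total fold sizes balance too) and is reproducible from the seed; the package
default seed is 20140901.

## Prognosis

`prognosis_by_rule()` stratifies a cohort by a panel rule and compares
time-to-event outcomes (relapse, hospitalization, surgery) between the
rule-negative and rule-positive strata: Kaplan–Meier curves
(`km_estimate()`), the log-rank test (`logrank_test()`) and a univariate Cox
model (`cox_univariate()`, Breslow tie handling by default — ties are rare in
the continuous simulated times; Efron is available). A stratum without events
makes the partial likelihood monotone; the estimate is flagged and its CI
reported unbounded rather than hidden. Published hazard ratios near 0.20
depend on unavailable patient data, so in this package they parameterize the
synthetic generator and define parameter-recovery tests; they are not treated
as reproducible constants.

## What the synthetic generator emulates

Because no patient-level data are deposited, `generate_cohort()` produces
cohorts with the statistical structure the analysis needs:

* **mSES-CD** is drawn from the published category histogram
  (97/19/54/57/3 over categories 0, 1–2, 3–4, 5–10, 11–15 — the tabulated
  counts, which sum to the analyzed 230, rather than the narrative text's
  n = 2 for the top category) and uniformly within category, because only the
  histogram is published. This yields 116/230 ≈ 50% remission.
* **Markers are log-normal conditional on remission status.** Strictly
  positive, right-skewed marginals match the published non-normality finding;
  each stratum has its own location *and* log-scale. The four parameters per
  marker are solved numerically (`solve_marker_mixture()`) so that the
  mixture hits the three published quartiles *exactly* — LRG 13.1 (8.5–16.7)
  µg/mL, CRP 0.10 (0.04–0.22) mg/dL, Fcal 202 (61–687) µg/g — while the
  stratum separation matches the published single-marker AUC (0.886 / 0.816 /
  0.876) through P(X_rem < X_act) = Φ((µ1−µ0)/√(σ0²+σ1²)).
* **Cross-marker dependence** is a Gaussian copula, the simplest mechanism
  that adds tunable dependence without disturbing the marginals. The
  within-stratum correlation is not published; the default of 0.3
  off-diagonal is a free parameter chosen once as a plausible residual
  dependence among inflammation markers.
* **Missing Fcal** (insufficient stool specimen) is missing completely at
  random at rate 38/268; no mechanism is published. Missingness is a
  first-class marker state, so the exclusion flow (`apply_exclusions()`,
  268 → 230) is reproducible and logged.
* **Follow-up** is exponential within rule stratum with configured hazard
  ratios 0.20 / 0.21 / 0.24 (relapse / hospitalization / surgery) and
  independent uniform censoring over 0.5–7 years, emulating staggered
  enrolment with a fixed analysis date; the baseline rates (0.080 / 0.030 /
  0.028 events per person-year in the unfavorable stratum) were chosen once
  so that expected event counts over that window approximate the published
  35 / 14 / 13 out of 230 with a median observation time near 3.6 years.
* **Demographics and CDAI** are matched on marginals only (CDAI: log-normal
  with median 135 and IQR ratio 179/58, weakly linked to severity). CDAI is
  not used by any rule; it is cosmetic realism.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: marker dependence on severity *within* the
remission/active strata (the generated marker–mSES-CD Spearman correlations
come out near 0.5–0.6, somewhat below the published 0.60–0.69, precisely
because of this conditional-independence simplification), treatment effects on
markers, longitudinal trajectories, informative missingness, and calendar-time
effects. Tests against synthetic cohorts validate the *machinery* (estimators
recover the parameters that generated the data); they cannot validate the
clinical cutoffs themselves.

## Numerical choices and degenerate inputs

* Youden ties break toward the smallest cutoff; thresholds are observed
  values only.
* Display rounding for table comparison is half away from zero
  (`round_half_away()`); all internal computation is full precision.
* Degenerate DeLong variance (identical placements, e.g. a marker compared
  with a monotone transform of itself) returns z = 0, p = 1 with a warning.
* The rank-sum test uses exact enumeration when both groups have at most 8
  observations and no ties, otherwise the tie-corrected normal approximation.
* A constant vector makes the Spearman coefficient undefined; it is returned
  as `NA` with a warning, never as 0.
* Marker values outside the assay quantitation ranges (LRG 5–100 µg/mL,
  Fcal 0.65–84000 µg/g) are flagged (`quantitation_flags()`), never clamped.
* Generation is a pure function of (config, seed); the global RNG state is
  saved and restored.

Problem sizes in the test suite and acceptance script were chosen as the
smallest that make each check informative: hand toys (n ≤ 8) for exact
oracles, the study size (n = 230/268) for study-shaped checks, n = 5000 for
hazard-ratio recovery (expected log-HR standard error ≈ 0.09, so the
interval [0.15, 0.27] is a meaningful bound around 0.20), and n = 100000 for
marginal recovery at 10% tolerance.

## Known limitations

* The per-item mSES-CD scoring rubric is not published; the package accepts
  totals directly and validates per-item scores only structurally (0–3, 6 × 3).
* Single-marker confidence intervals and p-values printed in the source study
  cannot be checked without the raw data; only the CI machinery is verified,
  on synthetic inputs.
* The DeLong-on-binary-predictions comparison of cross-validated rules is an
  approximation of an unstated published procedure, as is per-fold cutoff
  refitting; both are documented knobs.
* `run_pipeline()` is the orchestration surface (there is no shell
  executable): it writes per-stage CSV/JSON and a markdown report, and reruns
  byte-identically for a fixed seed.
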