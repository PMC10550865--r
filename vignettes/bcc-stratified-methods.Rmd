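---
title: "Methods: sex-stratified BCC analysis of thrombectomy outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified BCC analysis of thrombectomy outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccstrat)
```

# The problem

In acute ischemic stroke (AIS), endovascular thrombectomy (EVT) removes the
occluding clot mechanically; complete recanalization (TICI grade 3) is
achieved in roughly half of patients. Clot composition relates to stroke
etiology and to the circulating blood picture, and both differ between women
and men. `bccstrat` implements a seven-step analysis of whether routine
hematology-analyzer blood cell characteristics (BCCs) — counts, percentages
and morphology indices of leukocytes, erythrocytes, reticulocytes and
thrombocytes — relate to recanalization success differently in women and
men, and whether the same BCC clusters also separate cardioembolic (CE) from
large-artery atherosclerotic (LAA) stroke.

Because patient-level registry data of this kind cannot be distributed, the
package ships a synthetic-cohort generator whose planted ground truth makes
every stage testable: the analysis code never sees the truth, and tests
check that it is recovered.

# Pipeline

1. **Outcome labels.** TICI grades are text-mined from radiology reports
   (`extract_tici()`): spellings `TICI`/`mTICI`/`eTICI`, optional
   space/hyphen/colon, grades 0–3 with a/b/c subgrades. Exactly one
   distinct grade binarizes to success (grade 3) vs failure (0–2c);
   reports with no or several distinct grades are routed to manual
   labeling. Repeated mentions of the *same* grade count as unique — we
   read "more than one grade" as more than one *distinct* grade; the
   stricter reading (any repeated mention) would only enlarge the manual
   queue.
2. **Univariate sex screen.** Each BCC is compared between sexes
   (`screen_by_sex()`) with a two-sided Mann–Whitney U test and
   Benjamini–Hochberg FDR correction at q < 0.05. The rank test was chosen
   because hematology values are typically skewed and the natural
   summaries are medians/IQRs; a Welch t-test is available via
   `test = "t"`.
3. **Collinearity clustering.** BCCs are clustered on the distance
   1 − |Spearman ρ| with average-linkage hierarchical clustering
   (`select_k()`). The number of clusters k is chosen to maximize the
   *sex concordance* of the partition: women-only and men-only distance
   matrices are clustered separately at each candidate k and scored by the
   adjusted Rand index; ties go to the smallest k. The final partition is
   fitted on pooled data, and each cluster is represented by the mean of
   its z-scored members (deterministic sign and robust for two-member
   clusters; a first-principal-component representative would be nearly
   identical here but has an arbitrary sign).
4. **Sparse PLS-DA.** `fit_splsda()` is a from-scratch soft-thresholded
   NIPALS implementation: per component, the X-weight vector is the
   dominant direction of the X–Y cross-covariance (Y dummy-coded and
   centered), soft-thresholded at every power-iteration step to `keepX`
   nonzero entries (entries below the (keepX+1)-th largest magnitude are
   shrunk by that magnitude and zeroed), iterated to convergence
   (tolerance 1e-9, at most 500 iterations), then X and Y are deflated by
   regression on the component score. With `keepX` equal to the number of
   variables the first component coincides with the dominant singular
   direction of the cross-covariance, which the tests verify to 1e-6.
   Classes are predicted from the projected scores; the default `max_dist`
   rule takes the class with the largest predicted indicator value, with
   exact ties broken deterministically to the earlier class level. The
   sign of every weight vector is fixed (largest-magnitude entry positive)
   so fits are identical run-to-run.
5. **Stability selection.** `repeated_cv()` runs R repeats of stratified
   K-fold cross-validation (defaults K = 5, R = 100, mirroring fivefold
   CV repeated 100 times). Inside every training fold the cluster
   representatives are rebuilt from training-fold means/SDs (no leakage),
   `keepX` is tuned per component on an inner stratified 75/25 holdout of
   the training fold over the grid {5, 10, 15, 20, 25, 30}, the model is
   fitted and the held-out fold predicted. A cluster's selection frequency
   is the fraction of all K·R fold-fits whose component-1 weight for it
   was nonzero; the stable set is the clusters with frequency strictly
   above 0.9. Component-2 frequencies are reported but not thresholded.
   `stratified_comparison()` applies the same engine to the pooled cohort
   and to each sex and compares the three per-repeat error distributions
   with Welch two-sample t-tests (`welch_t()`).
6. **Etiology consistency.** `etiology_consistency()` reruns stability
   selection per sex with etiology as outcome, restricted to that sex's
   recanalization-stable clusters, and intersects the two stable sets.
   The contrast is binary CE vs LAA with undetermined strokes excluded —
   the two etiologies with distinct clot biology; a three-class run is
   available via `classes = c("CE", "LAA", "UND")`. Stable clusters get a
   direction label: the outcome class with the larger median of the
   cluster representative (exact ties are labeled `none`).
7. **Adjusted models.** `adjusted_effects()` fits, per stable cluster, a
   complete-case logistic model of success on the standardized cluster
   representative plus hypertension, hyperlipidemia, atrial fibrillation,
   diabetes, smoking, prior stroke/TIA, prior myocardial infarction,
   antiplatelet use, DOAC use and IVT, using the in-house IRLS routine
   `logistic_irls()` (deviance tolerance 1e-8, at most 50 iterations,
   Wald intervals from the inverse observed information). Coefficients
   diverging beyond |β| > 15 raise a separation error rather than a
   misleading estimate. Because published per-covariate estimates of this
   kind can be ambiguous between log-odds and odds-ratio scales, results
   report both (`beta`/`ci_*` and `or`/`or_*`). Age is not in the default
   adjustment set — the covariate list is configurable — and no imputation
   is attempted: complete-case analysis keeps the estimand simple and the
   missingness mechanism of the generator is MCAR, under which
   complete-case estimates are unbiased.

# The synthetic cohort

`bcc_config()` + `simulate_cohort()` generate, deterministically per seed:

* **BCCs**: 71 variables from a multivariate normal with block structure —
  58 blocks (13 pairs + 45 singletons), within-block correlation 0.9,
  between-block 0.1. This emulates strongly collinear analyzer channels
  (hemoglobin/hematocrit; impedance vs optical platelet counts) against a
  weak common background. A log-normal marginal option exists; rank-based
  stages are unaffected by it.
* **Sex shifts**: 21 BCCs shifted between sexes by 0.8 SD (whole pairs are
  shifted coherently so within-block correlations survive pooling),
  emulating the well-known sex differences in hematology reference
  intervals (e.g. platelets higher in women, hemoglobin lower).
* **Outcomes**: recanalization from a logistic model on standardized
  cluster representatives with sex-specific coefficients — by default 13
  shared, 12 female-only and 20 male-only informative clusters at a weak
  per-cluster log-odds of 0.15, chosen so that cross-validated error
  stays in the near-chance regime reported for real cohorts rather than
  collapsing to trivial separability; the intercept puts the success rate
  near 0.48. Etiology (CE/LAA/UND) comes from a multinomial logit with
  marginals ≈ 0.39/0.34/0.27 and cluster effects on the CE and LAA
  logits for a subset of the recanalization-informative clusters
  (3 shared, 12 female-only, 11 male-only).
* **Covariates**: independent Bernoulli draws at realistic EVT-cohort
  prevalences (hypertension 0.57, hyperlipidemia 0.41, atrial fibrillation
  0.17, …, IVT 0.34).
* **Reports**: one text per patient with a TICI mention consistent with the
  label; configurable fractions carry no mention (default 5%) or two
  conflicting grades (5%) to exercise the manual-labeling triage.
* **Missingness**: MCAR on BCC columns at a configurable rate (default 0 —
  BCC panels are analyzer-generated and essentially complete in practice).

What the generator does *not* emulate: instrument-level physics, realistic
hematology reference intervals and units, correlated covariates,
informative missingness, or the messy referral structure of a tertiary
center. Passing tests therefore demonstrate correctness of the machinery
and recoverability of planted structure, not clinical validity on real
registries.

# Problem sizes used in tests

The recovery and calibration suites use scaled-down but statistically
meaningful designs: stability-selection recovery uses 5 planted clusters at
log-odds 0.8, n = 300, K = 5, R = 25, 20 replicates; clustering recovery
uses the full 71-variable/58-cluster structure over a k-grid of 40–70 and
20 seeds; the sex-stratification contrast uses female-only effects of 1.0
across 20 seeds at R = 25. The acceptance script runs the full pipeline at
the default cohort size (333 patients) with R = 25 repeats.

# Numerical choices and degenerate inputs

* Soft-thresholding ties at the cutoff are broken by first index; in the
  measure-zero case where shrinkage would null every retained entry (an
  exactly tied block), the retained entries are kept unshrunk so a
  direction always exists.
* Scores across components are orthogonal by construction; the tests
  assert this to 1e-8.
* Constant columns: distance 1 to everything (clustering), excluded from
  cluster representatives, p = 1 by convention in the univariate screen.
* A candidate set too small to support the requested number of components
  truncates the fit with a warning instead of failing.
* Stratified folds require every class to have at least K members; the
  engine refolds defensively if a degenerate split ever occurs.
* The 60-minute BCC eligibility window is inclusive (a panel at exactly
  60 minutes is retained); unparseable timestamps exclude the row with an
  explicit `bad_timestamp` reason rather than aborting.

# Known limitations

* **Stability selection over CV folds is not null-calibrated
  per-dataset.** Training folds of a fivefold split share ~80% of their
  rows, so the selection of the strongest *noise* cluster is highly
  consistent across fold-fits: on null data (no planted outcome signal,
  n = 300, 58 clusters) the maximum spurious selection frequency exceeds
  0.9 in most datasets (a mean of about 1–2 spurious stable clusters of
  58 in our null experiments), even though planted-signal recovery is
  excellent. The 0.9 threshold should therefore be read as a *ranking*
  device, not as a false-positive guarantee; genuine null calibration
  would need disjoint subsamples or randomized penalties, which the
  repeated-CV scheme deliberately mirrors instead. The corresponding null
  expectation in the acceptance suite fails for this structural reason,
  and we keep it failing rather than weaken the check.
* The sex-concordance criterion for choosing k assumes the true
  correlation structure is identical in women and men; if it were not,
  the criterion would trade cluster resolution for agreement.
* Welch tests between pooled and stratified error distributions inherit
  the usual caveat that CV error estimates are not independent samples;
  they are used descriptively, as in common practice.
* The etiology contrast drops undetermined strokes by default, which
  shrinks the per-sex sample and can make small classes fail the
  class-count precondition on small cohorts.
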