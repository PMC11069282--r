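---
title: "Glycemic variability indices and 30-day mortality: methods"
author: "glycostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic variability indices and 30-day mortality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycostrat)
```

## The scientific problem

Hospitalized patients with type 2 diabetes mellitus (T2DM) are typically
switched to a basal–bolus insulin regimen, and their bedside (POCT) glucose
is measured pre-prandially at breakfast, lunch and dinner plus once at
bedtime. Two families of indexes summarize those measurements:

* **Glycemic variability (SD)** — the sample standard deviation of the
  in-hospital glucose series, in mg/dl.
* **Coefficients of variation (CV)** — the SD scaled by a mean glucose, in
  percent. The *in-hospital CV* divides by the in-hospital mean. The
  *estimated pre-hospitalization CV* instead divides by the pre-admission
  mean glucose inferred from admission HbA1c, linking in-hospital
  instability to the patient's chronic glycemic state:

  $$\mathrm{CV}_{\text{pre}} = 100 \cdot \frac{\mathrm{SD}_{\text{in}}}
  {\widehat{G}_{\text{pre}}}, \qquad
  \widehat{G}_{\text{pre}} = 28.7 \cdot \mathrm{HbA1c} - 46.7 .$$

The package reimplements, as a tested pipeline, an analysis relating these
indexes to 30-day in-hospital all-cause mortality in a cohort of 120
hospitalized T2DM patients: ROC-based stratification with univariate
statistics, multivariable logistic and Cox models, and an AdaBoost
decision-stump classifier with SMOTE balancing and feature augmentation.
Because the original patient-level data are not publicly deposited, a
seeded synthetic-cohort generator with plantable effects stands in for the
data source, and the published summary tables are reproduced exactly from
their printed counts (`verify_reference_tables()`).

## Glycemic indices

`summarize_glycemia()` computes, per patient: arithmetic mean, sample
median, sample SD (n−1 denominator), in-hospital CV, estimated pre-hospital
CV, the in/pre mean glucose ratio, and the Hirsch stability flag
(`3·SD ≤ mean`). Two conventions deserve note:

* **SD denominator.** The n−1 (sample) form is used: each series is a
  finite sample of an underlying glycemic process. The reference cutoff of
  42.55 mg/dl cannot adjudicate n vs n−1 without the raw data; the choice
  is therefore a package convention, applied consistently.
* **HbA1c conversion.** The ADAG linear regression
  `eAG = 28.7·A1c − 46.7` (mg/dl) is the standard published linear map; the
  coefficients are exposed as arguments so other calibrations can be
  swapped in. The domain is restricted to HbA1c ∈ [4, 15]% to keep the
  conversion physiologic.

An exact identity used as a test oracle: when the in-hospital mean equals
the HbA1c-derived pre-admission mean (`ratio_in_pre = 1`), the two CVs
coincide. Scaling the glucose series leaves the in-hospital CV unchanged
and scales the estimated pre-hospital CV proportionally.

The Charlson Comorbidity Index uses the original 1987 weights, with exactly
one of the uncomplicated/complicated diabetes terms contributing.
Age-adjustment (+1 per decade from 50, capped at 4) is available but off by
default, since the reference analysis does not state whether it was used.
Hypertension is tracked in the cohort but carries no Charlson weight.

Inclusion filters mirror the study design: at least 12 consecutive
pre-prandial glucose determinations, at least 48 hours of stay, and an
admission HbA1c. Exclusions are labeled with the first failing rule, in
that order.

## ROC cutoffs and univariate statistics

`roc_curve()` enumerates one operating point per candidate threshold
(below the minimum, each midpoint between adjacent distinct scores, above
the maximum), treating higher scores as higher risk; the trapezoid AUC
equals the Mann–Whitney concordance probability, an equivalence asserted in
the tests. `optimal_cutoff_closest_to_corner()` picks the threshold
minimizing $\sqrt{(1-\text{sens})^2 + (1-\text{spec})^2}$; ties break
toward the lower threshold (the more sensitive rule), a convention the
package documents because the source analysis is silent. The induced
partition is invariant under strictly monotone score transformations.

Univariate conventions, validated against the published tables:

* **2×2 comparisons** use the uncorrected Pearson chi-square. This is the
  variant that reproduces the printed p-values (0.039 for the estimated
  pre-hospital CV mortality split, 0.006 for dementia, 0.025 for
  metastatic malignancy) from the printed counts. With Yates correction
  none of them match.
* **Continuous comparisons** default to the Mann–Whitney U test (exact
  enumeration when both groups have ≤ 8 untied values, tie-corrected
  normal approximation otherwise), switching to Welch's t only when both
  groups pass a normality screen (Shapiro–Wilk and Lilliefors KS, either
  rejecting at α = 0.05 ⇒ non-normal). The routing is recorded in the
  result.
* **Percentages** are rounded half-up to one decimal, matching how the
  reference tables print (base R's round-half-to-even would turn 20.25
  into 20.2).

Two printed p-values (0.06 and 0.14 for the SD and in-hospital CV
mortality splits) do not match uncorrected Pearson on the printed counts
(which give 0.055 and 0.135); the test variant behind those two cells is
ambiguous and they are deliberately not asserted anywhere.

## Risk models

`logistic_fit()` is plain maximum-likelihood logistic regression (IRLS)
with Wald 95% CIs, `exp(β ± 1.96·SE)`. No penalization or Firth correction
is applied: the reference output exhibits near-separation (an odds ratio of
53 with CI 3.7–768), and mirroring that behavior requires leaving
separation uncorrected; fits with any |β| > 15 are flagged instead.
`cox_fit()` uses the partial likelihood with Efron tie handling — many
same-day deaths are expected at daily resolution — with follow-up
administratively censored at 30 days. Adjusted survival curves evaluate the
fitted model at covariate means for each stratum level.

Time origin is admission; for deceased patients the length of stay is the
day of death, so event time equals stay. Whether "days of stay" belongs in
a mortality model at all is an immortal-time concern; the pipeline includes
it in the logistic models (as the reference analysis does) and uses
age + sex + CCI adjustment for the Cox models.

## The AdaBoost-FAS classifier

Order of operations: stratified 75/25 split → min-max scaling fitted on
training rows (test values clipped to [0, 1]) → SMOTE on the training set
only → feature augmentation → LASSO selection → boosting. Choices that
matter:

* **SMOTE** (k = 5, the method's canonical default) raises the minority
  (deceased) count to the majority count by interpolating between minority
  nearest neighbors on the scaled features; binary features are rounded at
  0.5 after interpolation. Synthetic rows carry a flag and never enter any
  evaluation set — a property the tests audit.
* **FAS** adds squared terms for continuous features and products for
  every unordered feature pair (binary × binary products are logical
  ANDs). Selection is an L1-penalized logistic regression (glmnet) with λ
  chosen by 5-fold stratified cross-validated deviance; at least one
  feature always survives (largest-coefficient fallback at the smallest
  λ).
* **AdaBoost** is the classical discrete form: exhaustive search over
  (feature, midpoint threshold, polarity) for the minimum weighted error,
  vote weight $\alpha_l = \tfrac12\log((1-\epsilon_l)/\epsilon_l)$,
  multiplicative weight update, early stop at separation (ε = 0, with the
  vote weight computed at a floored error) or when no stump beats ε = 0.5.
  The candidate set includes the two **constant votes** (stumps whose
  leaves agree, as CART depth-1 trees permit). This matters: a ±1 vote
  ensemble without constant votes has a decision boundary whose intercept
  is tied to the sum of vote weights, and provably cannot represent
  XOR-style interaction labels even after augmentation with the product
  feature; with the constant vote it separates them in a handful of
  rounds. Ties in weighted error break by lower feature index, then lower
  threshold, then the polarity assigning survival to the low side —
  training is fully deterministic given the data.
* **Prediction** is `sign(Σ αₗ gₗ(x))` with −1 = deceased, +1 = surviving;
  a zero margin resolves to surviving (the majority class) and each such
  resolution is counted. AUC uses the continuous margin, not hard labels.
* **Model reliance** perturbs a *base* feature by resampling its test
  column with replacement, re-derives all squared/interaction features of
  that parent, and re-evaluates; reliance is mean perturbed error over
  baseline error. Reliance is computed on the held-out test set. An inert
  feature converges to reliance 1; the tests check calibration at 500
  repeats within ±0.05.

Baselines (`baseline_models()`): majority classifier, CART decision tree
(Gini, depth ≤ 5, small minimum split sizes appropriate to a 120-patient
cohort), the same tree on FAS features, a logistic classifier on the
LASSO-selected FAS features at threshold 0.5, and AdaBoost without FAS —
the comparison set of the reference analysis.

The reference test-set metrics (accuracy 0.856, sensitivity 0.75,
specificity 0.962, AUC 0.76) are **not** reproduction targets: they depend
on the undisclosed cohort. The package validates mechanism instead: stump
search against a brute-force oracle, the ensemble equation as a property,
the XOR mechanism behind FAS's advantage, SMOTE flag audits, and reliance
calibration.

## The synthetic cohort generator

`cohort_spec()` defaults encode the published cohort's marginals: n = 120,
mortality 17/120, age 78.4 ± 8.9 truncated at 18, HbA1c 7.0 ± 1.6
truncated to [4, 15], male 60%, smoking 36.7%, the stated comorbidity
prevalences, the home-treatment distribution, in/pre mean glucose ratio
1.12 ± 0.27 (truncated at 0.3), and lognormal stays with survivor mean
15.5 (SD 12.6) and deceased mean 9.3 (SD 4.6) days, rounded to whole days,
floored at 2 and capped at 60. Where the source states no value the
defaults are fixed once at field-plausible levels and documented here:

* **Within-patient dispersion**: each patient's in-hospital CV is uniform
  on [12, 45]% — spanning the reported stratum means (≈20% below the
  25.8% cutoff, ≈33% above) with realistic tails on both sides.
* **Glucose series**: four slots per day (breakfast/lunch/dinner/bedtime)
  for every day of stay, lognormal around the patient's latent in-hospital
  mean with the patient's latent CV; lognormal keeps values positive and
  right-skewed, as bedside glucose is.
* **Planted outcome effects** (log-odds): hemiplegia 2.5, dementia 1.4,
  male 0.9, in-hospital SD 0.02 per mg/dl — moderate versions of the
  directions the reference analysis reports, far below its near-separation
  estimates. The intercept is calibrated by monotone root-finding so the
  expected mortality equals the target rate to within 1e-6.
* **Death timing**: the deceased stay distribution *is* the time-to-death
  distribution (stay ends at death), matching how the reference table
  reports deceased stays; no separate death-day model is imposed.

What the generator deliberately does **not** emulate: comorbidity
correlations (flags are independent given their marginals; real
comorbidities cluster), slot-of-day glucose structure (no circadian or
post-prandial pattern), treatment effects on glycemia, and any joint
distribution beyond the stated marginals and planted effects. Passing
tests therefore demonstrate the *machinery* is correct under known
conditions, not that the synthetic cohort is clinically exchangeable with
a real one.

One property worth knowing when planting effects on glycemic covariates:
the death model uses the *latent* per-patient SD/CV, while a refit on the
realized series summaries sees those values with sampling noise
(≈ 50–60 measurements per patient), so recovered glycemic coefficients are
attenuated — classical errors-in-variables. Recovery and coverage tests
therefore plant effects on exactly-observed covariates (comorbidity flags,
sex); the attenuation itself is visible and expected when refitting on
realized summaries.

## Validation problem sizes

The test suite checks marginal recovery and intercept calibration on
cohorts of 20,000; CI coverage pools three planted logistic effects
(n = 10,000 cohorts) and two planted Cox effects (n = 3,000 survival
simulations) over 50 seeds each, expecting pooled coverage within
0.95 ± 0.03; oracle equivalence for the stump search runs 100 random
instances (n ≤ 50, p ≤ 5); reliance calibration uses 500 repeats. The
full simulated pipeline (n = 120, 100 boosting rounds) runs in a few
seconds and is checked for bit-level reproducibility across runs.

## Known limitations

* Percentages and p-values reproduce the published tables from printed
  counts; patient-level results on the original cohort are unverifiable in
  principle (data not deposited).
* The normality screen's Shapiro–Wilk subsamples above n = 5000, making the
  routing non-deterministic at extreme sizes; cohort-scale analyses are
  unaffected.
* `optimal_cutoff_closest_to_corner()` returns a midpoint of observed
  values; on a different sample the numeric cutoff shifts even when the
  induced partition is stable.
* The Cox models treat within-hospital death as the only exit; competing
  risks and time-varying glycemic exposure are out of scope.
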