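---
title: "Predicting visceral adipose tissue from simple clinical measurements"
author: "vatmars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting visceral adipose tissue from simple clinical measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vatmars)
```

## The problem

Visceral adipose tissue (VAT) — fat stored around the abdominal organs —
is the adipose depot most strongly linked to cardiometabolic risk, but
measuring it requires cross-sectional imaging.  The quantity of interest
here is the VAT area (cm²) on an axial CT slice at the L3 vertebral
level, a standard single-slice surrogate for total visceral fat volume.
`vatmars` implements a published anthropometric prediction model for
that quantity, the machinery used to derive and validate such models,
and a synthetic cohort generator that makes the whole pipeline
exercisable without patient data.

## The published model

The predictor is a multivariate adaptive regression splines (MARS)
model: a constant plus a sum of basis functions, each a coefficient
times a product of at most two *hinge* factors `max(0, ±(x − knot))`
and/or categorical indicators.  The shipped model uses four inputs —
female sex, waist circumference (WC, cm), hip circumference (HC, cm)
and BMI (kg/m²):

```{r}
published_vat_model()
```

Predicted VAT is the constant plus the seven contributions.  At a male
record with WC 111, HC 106 and BMI 25.9 every hinge and indicator is
zero, so the prediction equals the constant, 249 cm²:

```{r}
predict_vat(published_vat_model(),
            subject_record(sex = "male", wc = 111, hc = 106,
                           height = 175, weight = 25.9 * 1.75^2))
```

Two representational choices matter and are pinned by tests:

* The 7.18 term is active for women only, and the 0.459 interaction is
  a product of two hinges (zero unless WC < 111 *and* BMI < 28.4).  A
  flattened one-line rendering of the model that drops these conditions
  would contradict the property that the constant is the prediction
  when all basis functions vanish.
* Hinges use `max(0, ·)`, so predictions at a knot are identical from
  both sides and strict-versus-weak inequalities in the conditions are
  immaterial; the surface is continuous and piecewise linear.

BMI is recomputed from height and weight whenever both are available;
an explicit `bmi` column is honoured otherwise, and a conflict beyond
0.1 kg/m² triggers a warning with the computed value winning.
Predictions outside 0–700 cm² raise a plausibility warning (chosen from
physiological limits) but are returned unchanged; the model is not
otherwise guarded against extrapolation.

## Units

Storage is canonical throughout: cm, kg, mmHg, mg/dl, ng/ml, cm².
Index formulas convert internally — triglycerides and cholesterol to
mmol/l with the conventional constants 88.57 and 38.67 mg/dl per
mmol/l (overridable, since laboratories sometimes use rounded factors),
and lengths to meters where a definition requires it.

## The fitting engine

`fit_mars()` reimplements the classical two-phase MARS algorithm.

**Forward pass.**  Starting from the constant, each step adds the
(parent term × hinge pair at a candidate knot) or (parent term ×
categorical indicator) that most reduces the residual sum of squares,
with interaction degree capped at 2, no variable reused within a term,
and candidate knots restricted to observed data values.  Hinge pairs
enter jointly; the backward pass may later delete one member of a pair,
which is how unpaired terms arise in final models.  The pass stops at
the basis-function budget (default 20, matching the derivation it
emulates) or when the relative RSS improvement falls below
`forward_tolerance` (default 1e-4).

**Knot thinning.**  `min_span` is the minimum number of observations
between candidate knots.  The default 1 admits every interior data
value, which is exhaustive but quadratic-ish in cost; for cohorts in
the thousands we use `min_span = 25` (about 80 candidate knots per
predictor at n = 2000), a choice made once for all large-cohort
analyses in this package.  Candidate knots exclude the extremes of the
parent-active range, where a hinge would be supported by too few
points.

**Backward pruning.**  Terms are deleted one at a time, always the one
whose removal yields the lowest generalized cross-validation score

GCV = MSE / (1 − C(M)/n)²,  C(M) = M + penalty · (M − 1),

with M counting terms including the constant and `gcv_penalty = 3`, the
conventional cost when interactions are permitted.  Coefficients are
re-estimated by least squares at every step and the GCV-minimal model
over the whole deletion sequence is returned.  A GCV-based criterion is
the canonical MARS choice; significance-based backward selection is a
plausible alternative that can prune more aggressively, and the two do
not always agree on marginal terms.

**Variable importance** is the total GCV increase caused by deleting
the final model's terms along the pruning sequence, credited to each
variable of the deleted term and normalized so the leader scores 100.
Ties break alphabetically; only variables in the final model appear.

**Cross-validation.** `kfold_cv()` shuffles with a seed, splits
contiguously, trains on each complement and reports per-fold and pooled
out-of-fold R² and RMSE.

Numerical choices: least-squares refits go through LAPACK QR;
exactly collinear candidate columns are skipped (and collinear members
of a hinge pair dropped) with a trace entry; candidate comparisons use
strict improvement, so ties resolve to the smallest knot, then the
predictor order as supplied — the whole fit is deterministic for a
given input and configuration.

## Comparator indices

`adiposity_indices()` computes VAI, LAP, ABSI, BRI, METS-IR, METS-VF,
WHR, WHtR and BMI with explicit unit contracts.  Three definitional
points:

* **ABSI** uses WC and height both in meters, the original definition;
  this matches the ~0.08 magnitude such cohorts report.  A
  centimeter-height variant differs only by a constant factor and would
  leave every rank-based analysis unchanged.
* **METS-IR** is `ln(2·glucose + TG) · BMI / ln(HDL)` with analytes in
  mg/dl — BMI multiplies the logarithm, the only reading consistent
  with METS-VF values near 6.5.
* **LAP** is negative when WC is below the sex constant (65 cm men,
  58 cm women); the value is retained rather than truncated, since
  truncation would silently discard ordering information.

## Metabolic syndrome

`classify_mets()` applies the NCEP ATP III component criteria:
abdominal obesity (WC strictly above 102/88 cm for men/women), raised
triglycerides (≥ 150 mg/dl), low HDL-C (< 40/50 mg/dl), raised blood
pressure (≥ 130 or ≥ 85 mmHg, or treated), raised fasting glucose.
The glucose cut defaults to the revised 100 mg/dl; the original
110 mg/dl is one argument away.  Boundary conventions (strict waist,
inclusive others) are documented and test-pinned because counts at
boundary values depend on them.

## ROC analysis and model evaluation

`roc_auc()` estimates the AUC by the Mann–Whitney placement estimator
with ties counted ½ and its standard error from the per-observation
placement components (the DeLong variance); `delong_test()` compares
two markers on the same subjects through the covariance of those
components, with a two-sided normal p-value.  Identical markers give
z = 0, p = 1 by convention.  `select_cutoff()` maximizes Youden's J
over the observed score values — candidates are data values, not
midpoints, which keeps the choice invariant under monotone transforms —
breaking ties toward balanced sensitivity/specificity and then the
smaller cutoff.  Positive calls use `score ≥ cutoff`; sensitivity and
specificity at boundary scores depend on that convention, so it is
stated.

`gof()` reports a thirteen-measure battery.  Most definitions are
standard; two deserve a note.  The relative approximation error is
RAE = Σe²/Σy², and the *mean* relative approximation error is
implemented as `sqrt(RAE / n)`.  Per-observation alternatives such as
`mean(|e|/y)` duplicate MAPE up to a factor 100 and cannot sit two
orders of magnitude below it, as this battery's reported values do;
`sqrt(RAE/n)` is the reading that keeps the battery internally
consistent, and the package adopts it.  AIC uses the least-squares
form `n·ln(SSE/n) + 2p` with p counting terms including the constant,
and CAIC its small-sample correction.  `calibration()` regresses
observed on predicted and reports the slope, the free intercept, R²,
and the calibration-in-the-large mean difference — both offset
conventions are reported because published calibration summaries do not
always say which they used.

## The synthetic cohort generator

`generate_cohort()` emulates the derivation study's conditions: 58.4%
women; per-sex means and SDs for age, WC, HC, BMI, blood pressures,
glucose, triglycerides and HDL-C taken from the study group's
gender-stratified descriptives; and "measured" VAT equal to the
published model's prediction plus Gaussian noise with SD 41 cm², the
model's reported residual scale, floored at 1 cm².  Height (173 ± 7 cm
men, 160 ± 7 cm women) and fasting C-peptide (2.1/2.0 ± 0.8 ng/ml) are
not reported in those descriptives and use typical adult values chosen
once.  Weight is derived from BMI and height.

The joint structure is a per-sex Gaussian copula: a correlation matrix
with typical cardiometabolic magnitudes (WC–BMI 0.85, WC–HC and BMI–HC
0.80, WC–TG 0.35, WC–glucose 0.30, WC–HDL −0.30, TG–HDL −0.40, age–WC
0.20, C-peptide–BMI 0.40, 0.10 elsewhere; projected to the nearest
positive semi-definite matrix), with truncated-normal marginals over
physiological bounds (e.g. glucose 60–125 mg/dl, reflecting a
diabetes-free cohort; TG 30–600).  Truncating a normal shifts its
moments, so each marginal's underlying mean and SD are calibrated
(by solving the truncated-moment equations) so that the *truncated*
distribution reproduces the target mean and SD exactly — plain
rejection sampling would bias, e.g., the TG mean upward by several
mg/dl.  A `dysmetabolism_shift` dial moves WC, TG, glucose and blood
pressure up and HDL-C down in SD units, for stress-testing the
metabolic-syndrome classifier.

What the generator does *not* emulate: the real skew of TG and VAT
(marginals are truncated normal; heavier-tailed options would change
index distributions but not the model's algebra), heteroscedastic VAT
residuals (real prediction errors grow at low VAT), and any real-world
measurement error structure.  Tests passing on synthetic cohorts
therefore validate the algebra, the algorithms and their statistical
calibration — not clinical performance on real patients.

## Simulation-backed behaviour and known limitations

Under the default conditions (n = 2000 cohorts, noise SD 41, 20
replicate seeds, `min_span = 25`), refitting data generated from the
published model shows the expected qualitative behaviour with two
caveats worth knowing:

* The final model almost always contains the generating knots — a WC
  knot within ~3 cm of 111 and a BMI knot within ~1 of 25.9 — but
  greedy forward selection typically *represents* the surface with
  additional auxiliary knots, because hinge pairs at interior points
  can reproduce a piecewise-linear surface in many ways.
* GCV pruning at penalty 3 retains, in a substantial fraction of
  replicates, one or two tiny nuisance terms (importance below 1)
  involving predictors outside the generating four.  This is the known
  selection-bias behaviour of GCV-pruned MARS: the best of thousands of
  candidate spurious terms looks better than its deletion cost.  A
  significance-based pruning step would remove such terms but is not
  the canonical criterion and is not implemented.
* Variable-importance attribution on these synthetic cohorts ranks BMI
  first (WC has the larger univariate R², about 0.56 against 0.44, but
  BMI's steep hinge slopes carry more conditional variance given the
  0.85 WC–BMI correlation).  Importance rankings on MARS models are
  representation-dependent and should be read qualitatively.

The DeLong paired test is calibrated: under a simulated null (two
independent noise markers, 500 subjects, 5000 replicates) the observed
type-I error at α = 0.05 sits within [0.04, 0.06].  The AUC estimator
agrees exactly with brute-force pair counting, and its variance with a
bootstrap, at the sizes the test suite runs.

Problem sizes in the shipped tests (up to n = 20,000 for generator
moments, n = 2000 × 20 seeds for refitting, 5000 replicates for test
calibration) were chosen as the smallest sizes at which these
statistical statements are stable.
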