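---
title: "Encoding repeatedly measured predictors for fixed-outcome prediction"
author: "longpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding repeatedly measured predictors for fixed-outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many cohort studies measure a predictor repeatedly — a child's BMI standard
deviation score (SDS) at every preventive health visit, say — and then want a
prediction model for a single fixed outcome years later, such as overweight at
age 10. Ordinary prediction modelling offers no canonical way to feed a
*trajectory* into a regression: the analyst must first encode the repeated
measurements into a fixed set of predictors. `longpred` implements six such
encodings, the supporting machinery around them (LMS z-scoring, broken-stick
regularisation onto a knot grid, collinearity-pruned model fitting,
Nagelkerke/adjusted R² and AUC with DeLong comparisons), and a synthetic
cohort generator so the whole comparison can be exercised end to end.

## From raw measurements to a complete knot matrix

**LMS conversion.** Raw measurements are made age- and sex-comparable with
the LMS method: a reference summarises, per age, the skewness `L`, median `M`
and coefficient of variation `S` of the measurement distribution, and

\[ z = \frac{(y/M)^L - 1}{L\,S}, \qquad z = \frac{\log(y/M)}{S} \text{ as } L \to 0. \]

`lms_zscore()` switches to the logarithmic form when `|L| < 1e-7`; the two
forms then differ by less than machine-level amounts over the usual ±3 SDS
range, so the switch introduces no visible discontinuity. Reference
parameters are interpolated linearly on the age axis (`lms_interpolate()`;
natural cubic splines are available via `method = "spline"` but linear is the
default because the boundary rule is linear and the two agree closely on
dense reference grids). Below the first reference age the parameters are
linearly extrapolated from the first two rows — infant references often start
at 1–2 weeks while birth measurements exist — but extrapolation above the
last reference age is refused: there is no analogous justification at the
upper end.

**Broken-stick regularisation.** Visits happen at irregular ages with gaps,
while most encodings need every subject valued on one fixed age grid. The
broken-stick model is a linear mixed model on the hat-function basis
\(B(t)\) over knots \(t_1 < \dots < t_k\):

\[ y_{ij} = B(t_{ij})^\top (\beta + b_i) + e_{ij}, \qquad
   b_i \sim N(0, G), \quad e_{ij} \sim N(0, \sigma^2). \]

The coefficients *are* the subject's values at the knots, so the empirical
Bayes predictions \(\hat\beta + \mathbb{E}[b_i \mid y_i]\)
(`predict_knot_values()`) fill a complete subjects × knots matrix, borrowing
strength from the population for sparsely observed subjects. The default
knot grid is birth, 3 m, 6 m, 14 m, 2 y, 3 y and 5.5 y — the scheduled ages
of preventive child health visits (months convert as m/12, so 14 months is
1.1667 y).

Estimation details that required genuine choices:

* **REML via `lme4`, unstructured covariance.** The 7-knot unstructured
  model has 28 covariance parameters; `cov_structure = "diagonal"` and
  `"cs"` (compound symmetry) are available for small cohorts. REML is the
  default because it is the standard, deterministic choice for mixed models;
  `method = "ml"` is available.
* **EM fallback.** A closed-form EM estimator (maximum likelihood, with the
  covariance structure imposed by projection in the M-step) takes over when
  the lmer optimiser fails, does not converge, or terminates on a singular
  boundary with collapsed residual variance. The last case matters for
  noiseless or near-noiseless data: a singular \(G\) with \(\sigma^2 \to 0\)
  cannot reproduce fully observed subjects, while the EM solution can.
* **Numerically stable BLUPs.** The textbook form
  \(G X^\top (X G X^\top + \sigma^2 I)^{-1} r\) is catastrophically
  ill-conditioned when \(\sigma^2\) is tiny. Predictions are computed through
  the eigendecomposition of \(X G X^\top\) with null-space components
  truncated (they contribute exactly zero in exact arithmetic because
  \(X G X^\top u = 0\) implies \(G X^\top u = 0\) for PSD \(G\)); in the
  noiseless limit a fully observed subject is interpolated exactly.
* **No extrapolation.** Records outside the knot span are dropped with a
  logged count; basis segments are left-closed, so an age equal to a knot
  belongs to that knot.

## The six encodings

Given the complete wide matrix \(x_{i1}, \dots, x_{ik}\) (and, for the
growth-curve method, the original long records):

1. **All measurements** (`feat_all()`): every knot column is its own
   predictor.
2. **Single measurement** (`feat_single()`): one chosen column.
   `select_single_best()` automates the choice by fitting univariable
   logistic models and picking the knot with the highest training AUC; a
   fixed index can always be forced.
3. **Summary** (`feat_summary()`): the per-subject mean or maximum.
4. **Changes** (`feat_change()`): the first value plus successive
   differences \(x_j - x_{j-1}\); `rate = TRUE` divides each difference by
   the elapsed time. Cumulative summation inverts the coding.
5. **Conditional measurements** (`feat_conditional_fit()`): for each
   \(j \ge 2\), the residual of \(x_j\) regressed (with intercept, across
   subjects) on \(x_1, \dots, x_{j-1}\). The intercept guarantees mean-zero
   residuals, which is what makes "uncorrelated with all earlier
   measurements" hold including the constant. The fitted coefficients are a
   transformer (`feat_conditional_apply()`) so new subjects are encoded with
   *frozen* training coefficients — refitting on new data would silently
   change the meaning of the features. Within the training set the frozen
   and refitted versions coincide.
6. **Growth-curve parameters** (`feat_growthcurve()`): per subject, an OLS
   polynomial of SDS on age (degree 1–3), giving features
   (mean, \(b_{age}\), \(b_{age^2}\), \(b_{age^3}\)), optionally plus the
   standard error of the linear slope as a fluctuation indicator. Ages are
   centred at the subject mean internally and coefficients mapped back, so
   reported values are raw-basis. The "mean" is the mean of the measurements
   actually fitted (the long records when long data are supplied, the knot
   values when a wide matrix is). Saturated fits (exactly `degree + 1`
   points) get `se_slope = 0`; subjects with fewer points are an error by
   default or are demoted to the highest feasible degree with a warning
   (`demote = TRUE`, used by the workbench). The phrase "standard error of
   the slope" is ambiguous between the coefficient SE and the residual
   scatter; both are implemented (`se_type = "slope"` / `"residual"`), with
   the coefficient SE as default.

Encodings 1, 4 and 5 are invertible affine maps of the same \(k\) columns.
Any GLM fitted on them therefore has identical fitted values, likelihood,
AUC and unadjusted R² — which is exactly why comparisons of this kind report
identical performance for those three methods. This equivalence is asserted
to 1e-8 in the test suite and is a useful internal consistency check on the
whole fitting path.

## Prediction models and performance

`fit_predmodel()` fits plain maximum-likelihood logistic or OLS linear
models (no shrinkage) after `drop_aliased()` has removed columns that are
numerically in the span of the intercept plus previously entered columns
(relative tolerance 1e-8, later-entered columns dropped). This mirrors the
automatic collinearity removal of standard regression software; since
software differ in *which* column of a dependent set they discard, the
entry-order rule is made explicit here. With heavily smoothed broken-stick
matrices such drops genuinely occur.

Performance follows the conventions of clinical model comparison:

* `auc()` is the Mann–Whitney estimate (ties 0.5), computed via midranks —
  identical to exhaustive pair counting.
* `nagelkerke_r2()`:
  \(R^2_N = (1 - e^{-LR/n}) / (1 - e^{2\ell_0/n})\) with
  \(LR = 2(\ell - \ell_0)\). The "adjusted" variant penalises the
  likelihood-ratio statistic by the model degrees of freedom
  (\(LR \mapsto \max(0, LR - p)\)). This df-penalty is an interpretation of
  the adjusted label; because reasonable readers could also take it as a
  bootstrap-optimism correction, the unadjusted value is always reported
  alongside so either reading is inspectable.
* `adjusted_r2()` is the usual \(1 - (1-R^2)(n-1)/(n-p-1)\).
* `delong_test()` compares two correlated AUCs via placement values, with
  the covariance of the two sets of structural components, a two-sided
  normal p-value and no continuity correction. Linear models are compared on
  discrimination by scoring their continuous predictions against the
  observed binary label.

All workbench performance is *apparent* (fit and evaluate on the same
cohort); no bootstrap optimism correction or cross-validation is provided,
deliberately, because the comparison of encodings is about relative
behaviour on one dataset.

## The synthetic cohort generator

Real growth-cohort data of this kind are generally not redistributable, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, and its defaults are the package's fixed reference study
conditions: 730 subjects on the 7-knot grid; true knot values
\(\mu + b_i\) with \(\mu = (-0.6, -0.4, -0.4, 0.2, 0.1, -0.1, -0.2)\) SDS,
per-knot SDs (0.9, 0.8, 0.8, 0.8, 0.8, 0.8, 0.7) and correlation decaying as
\(0.8^{|i-j|}\) between knots (successive body-size measurements are highly
correlated; the decay constant is a modelling choice, not an estimate);
visit ages jittered around the knots (SD 0.05 y, clamped to the span);
measurement noise 0.1 SDS; 20% of visits missing completely at random, with
the two-visit minimum enforced by redrawing a subject's missingness mask;
47% boys. The outcome is \(w^\top b_i\) + noise at an age drawn uniformly in
9–10.5 y, dichotomised at its empirical 87.7% quantile so the positive
("overweight") fraction is 12.3% by construction — a prevalence quantile is
used instead of external BMI cut-off tables because those tables are
third-party reference data, and the prevalence is the reproducible anchor.

The default outcome weights \(w = (0, 0, 0, 0, 0.05, 0.15, 0.8)\) put almost
all signal on the late knots, and the noise SD (0.9) is chosen so the
full-trajectory logistic model attains an AUC near 0.8. Together these
reproduce the qualitative ranking that motivates the package: the mean and
maximum summaries discriminate clearly worse than the full trajectory, while
the last measurement alone comes within 0.02 AUC of it.

`scenario()` provides three alternative regimes for the predictor–outcome
relation: `"trajectory_driven"` (a zero-sum contrast across knots — only the
*shape* carries signal, so level summaries fail and slope-bearing encodings
win), `"level_driven"` (equal weights — the subject mean is essentially
sufficient), and `"extreme_driven"` (the outcome follows the subject's peak
value — the maximum summary is the natural encoding; this required an
`outcome_form = "max"` switch since a peak is not a linear functional of the
knot values).

Randomness is organised as one master seed with deterministic per-stage
substreams (sex, trajectories, jitter, noise, missingness, outcome), so the
same seed reproduces a cohort bitwise and adding a stage never perturbs
earlier draws.

What the simulator deliberately does **not** emulate: informative
missingness (visits are missed at random, while real clinic attendance
correlates with growth concerns), raw-BMI measurement error on the original
scale (the analysis operates on SDS throughout; raw-scale fixtures for LMS
testing are built through the inverse z-score), secular trends, and any
nonlinear predictor–outcome link beyond the peak-value scenario. Passing
tests on these cohorts therefore show that the machinery is correct under
the stated model, not that any particular encoding will win on a given real
dataset.

## Numerical and policy details worth knowing

* Outcome selection (`select_outcome()`): within the 9–10.5 y window the
  record closest to age 10 wins; exact distance ties go to the earlier
  record (documented convention).
* Inclusion (`apply_inclusion()`): subjects need at least two records in the
  predictor span; exclusions are counted.
* Aliasing tolerance 1e-8 (relative); logistic IRLS tolerance 1e-10 with a
  100-iteration cap; (quasi-)separation is flagged with a warning and the
  capped-iteration coefficients returned.
* JSON serialisation of models and transformers uses 17 significant digits,
  so round-trips are exact at double precision.
* The workbench's default growth-curve encoding is cubic, with subjects
  lacking four distinct ages demoted rather than dropped, so the comparison
  grid stays complete.

## Problem sizes in the test suite

The suite exercises parameter recovery at 500 subjects on the full 7-knot
grid, the recoding-equivalence property across 50 simulated cohorts of 730
subjects, the qualitative method ranking and the scenario suite at 2000
subjects, DeLong-vs-bootstrap agreement on twenty 200-subject instances
(2000 stratified resamples each), and exact AUC pair-counting up to 200
subjects. These sizes were chosen to keep Monte-Carlo error well inside the
asserted tolerances while remaining comfortable to run routinely.

## Known limitations

* The broken-stick fit smooths: BLUP knot values are shrunken versions of
  the truth, so encodings computed from them can order slightly differently
  than on fully observed data. This mirrors the real analysis situation.
* Compound-symmetry covariance is fitted by the EM engine only.
* `nagelkerke_r2(adjusted = TRUE)` is one defensible reading of an
  "adjusted" Nagelkerke R²; see above.
* Apparent performance only; external or internal validation is out of
  scope.
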