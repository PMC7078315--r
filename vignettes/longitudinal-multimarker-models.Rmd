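---
title: "Longitudinal multimarker trend models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal multimarker trend models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markertrend)
```

## The problem

Single serum measurements of tumour markers such as CA125 make poor screening
tests: levels vary far more between women than within one woman over time, so
a population cut-off is insensitive to a marker that has doubled from a low
personal baseline. Serial measurements from annual screening visits carry that
within-person information. This package implements a longitudinal analysis for
nested case-control screening data: each woman's per-marker trajectory is
collapsed into scalar *trend indices*, multimarker logistic models over those
indices are searched exhaustively under leave-one-out cross-validation, and
the winners are compared against the conventional final-measurement cut-off.

## The trend indices

A marker series for one subject is the ordered set of pairs
$(t_j, y_j),\ j = 1 \dots k$, with $t_j$ the age at the $j$-th annual visit
and $y_j$ the $\log_{10}$ concentration. Five indices summarise it:

1. **Mean derivative** $\frac{1}{k-1}\sum_{j<k} \frac{y_{j+1}-y_j}{t_{j+1}-t_j}$ —
   the average year-on-year gradient. On any exact line it returns the slope.
2. **Area** $\frac{1}{k-1}\sum_{j<k} (t_{j+1}-t_j)\frac{y_j+y_{j+1}}{2}$ —
   the average per-interval trapezoidal area under the series.
3. **Coefficient of variation** $\mathrm{sd}(y)/\mathrm{mean}(y)$ — time-free
   dispersion relative to the personal level; scale invariant.
4. **Centre of mass** $\sum_j t_j y_j / \sum_j t_j$ — an age-weighted mean
   level, damping any age trend in the marker.
5. **Final value** $y_k$ — the conventional cut-off feature.

Features are named `MARKER{index}`; the reference model `CA125{5}` is a
logistic model on the final CA125 measurement alone.

Two of the verbal definitions admit a second algebraic reading, so both are
implemented behind explicit arguments. For index 1, weighting each gradient
by its interval length telescopes to the chord slope
$(y_k-y_1)/(t_k-t_1)$, which discards all interior points and makes
"consecutive pairs" vacuous; the unweighted mean is therefore the default and
the telescoping form is available as `index1_variant = "telescoping"`. For
index 2 the default is the per-interval trapezoid average; the alternative
$\sum_j (t_k-t_j)y_j / k$ is available as `index2_variant = "sum_to_end"`.
Index 4's denominator uses the ages themselves (not age differences),
following the literal definition. Indices are computed on $\log_{10}$ values;
because a coefficient of variation is unstable when its denominator
approaches zero, `index3_cv()` warns when $|\mathrm{mean}(y)| < 0.1$.
Indices 1–3 are undefined (not zero) for single-visit series; such units are
dropped, with a count, from any model that needs them.

## Sample-inclusion rules

Model building uses only annual screening samples — repeat samples triggered
by an elevated risk score would enrich the case series with rising
trajectories and bias the comparison. Case samples taken more than 60 months
before diagnosis are dropped (the boundary value 60 is retained); borderline
tumours are excluded entirely; controls are never excluded by time rules.
Two evaluation windows are defined: *within 1 year* keeps cases whose final
retained annual sample falls $\le 12$ months before diagnosis, and
*1–2 years* first deletes all case samples $\le 12$ months before diagnosis
and then requires the new final sample to fall $\le 24$ months before it.
Closed bounds are used throughout; time to diagnosis is carried in months
and converted to years by exactly 12.

## Variable selection and model search

Five criteria nominate candidate features from the terminal feature matrix:
bidirectional AIC stepwise selection from the intercept-only logistic model;
the lasso with its penalty chosen as the first value on the grid
$\lambda = 0, 0.01, 0.02, \dots$ that leaves at most three variables active;
a 200-resample stratified bootstrap of that lasso rule, scoring each feature
by its inclusion frequency; and random-forest permutation (mean decrease in
accuracy) and Gini importances from a 500-tree forest. Features are
standardised before penalisation — the indices live on incomparable scales,
and an unstandardised L1 penalty would simply select the largest-scaled ones.
The five criteria are combined by a union rule: AIC picks, lasso picks, and
the top `top_m` (default 5) features per ranked criterion, with ties broken
by feature name. The union rule and `top_m` are this package's choice; they
are exposed in `selection_config()` and recorded in every run summary.
Bootstrap resampling is stratified by case/control status so no resample is
single-class. All selection operations canonicalise row order before
touching the random-number stream, so results cannot depend on the order in
which units arrive.

Every subset of one to three pool features is then fitted as a main-effects
logistic model and cross-validated leave-one-subject-out: the analysis unit
is the subject, so in rolling evaluations all of a subject's visit rows
leave the training set together and no within-subject information leaks into
its own fold. A training fold that loses a class falls back to an
intercept-only model predicting the fold prevalence. Models are ranked by
cross-validated sensitivity at 0.903 specificity (cross-validated AUC is
available), with ties broken in favour of fewer features, then by name.
Perfect separation — common at these sample sizes with strongly rising
markers — is flagged, and flagged fits are refitted with a tiny ridge
penalty ($10^{-6}$, intercept unpenalised) purely for numerical stability of
the scoring rule; the flag is retained in the fit metadata.

## Evaluation

The decision threshold at target specificity $s$ is the smallest value with
at least a fraction $s$ of control scores strictly below it; scores at or
above the threshold are positive, so ties count against the model's
specificity claim. By default the control scoring unit is the *visit*: with
175 control annual samples, thresholds leaving 158 or 167 of them below
reproduce the conventional 0.903 and 0.954 specificity levels, which 31
control subjects alone cannot form. That reading is an inference, not a
given, so subject-level specificity is retained as `spec_unit = "subject"`.
Case positivity always uses the subject's final eligible unit. Confidence
intervals for sensitivity come from 2000 stratified bootstrap replicates in
which *both* the threshold and the sensitivity are recomputed, and the
bootstrap median is reported alongside the plug-in estimate. AUC is the
tie-corrected Mann–Whitney statistic with a DeLong-variance Wald interval.
Paired model-versus-reference comparison uses the exact one-tailed McNemar
test on case calls at matched specificity (`b` = cases caught by the model
only, `c` = by the reference only; $p = P(X \ge b),\ X \sim \mathrm{Bin}(b+c,
\tfrac12)$), with the one-sided alternative that the model is more
sensitive. Calibration is the Hosmer–Lemeshow decile test with tied
probabilities kept together and zero-variance groups merged downward. The
univariate screen gates on the D'Agostino–Pearson omnibus normality test at
$\alpha = 0.05$ in both groups (implemented from the standard skewness and
kurtosis Z transformations), choosing a Welch t-test or a Mann–Whitney
test; groups below $n = 8$ default to Mann–Whitney because the kurtosis
approximation fails there.

## Lead time

Case scores from the rolling feature matrix are pooled and smoothed by loess
(tricube weights, degree 2) against years before diagnosis, with pointwise
95% bands, on a 200-point grid. The crossing time is, scanning from the
earliest time toward diagnosis, the first time after which the curve stays
at or above the positivity threshold through to diagnosis — a sustained
crossing, so an isolated early blip does not count; a `first_touch` rule is
available. Lead-time gain is the difference between the model's and the
reference's crossing times, in months, positive when the model turns
positive earlier (i.e. further from diagnosis). The default span is 0.75
for display smoothing; for crossing estimation against change-point
structure a span of 0.3 localises the kink and is what the validation
experiments use. Controls are plotted against years since final sample but
never enter crossing estimation.

## The synthetic cohort generator

Because the original assay data are not publicly deposited, validation runs
on a generative stand-in with known truth. Each subject has annual visits at
entry age $+ 0, 1, 2, \dots$ years with small truncated jitter
(SD 0.03 yr); entry ages are Normal(61, 4), placing sample-draw ages in the
observed post-menopausal range. Case diagnosis falls uniformly 0–12 months
after the final visit, so the within-1-year evaluation rule is exercised by
default. Each marker's $\log_{10}$ concentration is a subject-specific
baseline (between-subject SD 0.15–0.30 $\log_{10}$ units by marker) plus,
for cases, a linear rise of marker-specific slope beginning at a
change-point $\tau$ months before diagnosis, plus measurement noise with SD
$\log_{10}(1+\mathrm{CV})$ — the small-CV approximation to multiplicative
assay error, using each assay's reported intra-assay CV (4–22%). The default
panel has ten markers sized 31 controls / 9 Type I / 30 Type II /
10 borderline; CA125, HE4, CHI3L1, PEBP4 and AGR2 rise (fastest for Type II
disease, e.g. CA125 at 0.45 $\log_{10}$/yr from 24 months out), while LRG1,
FSTL1, SLPI, glycodelin and DNAH17 are flat.

The deterministic change-point-linear form was chosen because it admits an
exact analytic oracle (`oracle_scores()`) for parameter-recovery tests; it
is a stand-in, not a claim about real marker kinetics. What the generator
deliberately omits: age trends in baselines, assay batch effects, missed
visits and irregular sampling, case-control matching structure (both groups
share one age distribution), benign conditions that raise markers in
controls, and any biological within-subject variation beyond assay noise.
Passing tests therefore demonstrate that the machinery recovers structure it
is designed to detect — not that real screening data contain that structure.

## Numerical choices and degenerate inputs

Grid step 0.01 and an upper grid bound just above the smallest
full-shrinkage $\lambda$ define the lasso scan; the path is fitted at
convergence threshold $10^{-8}$, at which the active sets match
independently refitted per-$\lambda$ models on test instances. LOOCV refits
warm-start from the full-data coefficients. Predictions are clamped to the
open unit interval at $10^{-12}$. Thresholds at target specificity 0 return
$-\infty$ (everything positive). Hosmer–Lemeshow refuses fewer than three
distinct probabilities or $n < 2\times$ groups. Loess failures on sparse
data raise an error suggesting a larger span. Empty filter results warn
rather than error, since filtering may legitimately empty a stratum.

## Problem sizes used in validation

The test suite generates all data programmatically: index oracles run on
1000 random series; null simulations use 50 replicates at $n$ = 60–500;
parameter recovery uses 20 cohorts of 93 controls and 84 cases (three times
the evaluation-set scale) with 3 informative and 7 noise markers; lead-time
recovery uses 40-case cohorts with an 18-month change-point offset; and the
end-to-end determinism check runs a 27-subject pipeline twice. These sizes
were chosen to give the statistical assertions comfortable power while
keeping a full validation run on one core in the minutes range.

## Known limitations

Selection, search and evaluation reuse the same cohort, as in the original
design; reported cross-validated sensitivities are honest about fold overlap
but not about selection-induced optimism, which only an outer validation
cohort could remove. The exhaustive search is limited to three main effects;
no interactions or splines. Leave-one-out probability predictions are
pessimistic under the null: holding out a case lowers the training
prevalence, so null cross-validated AUC sits below 0.5 rather than at it — a
conservative artifact (models never look spuriously good), but one to keep
in mind when reading absolute cross-validated AUCs for weak models. Calibration of separated models is undefined
(their probabilities are degenerate) and is reported as `NA`. The lead-time
estimate is a population-curve crossing, not a subject-level survival
quantity, and inherits loess boundary bias near the extremes of the observed
time range.
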