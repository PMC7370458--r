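---
title: "Mapping QLQ-C30 onto EQ-5D-3L utilities: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QLQ-C30 onto EQ-5D-3L utilities: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolmap)
```

## The problem

Cost-effectiveness models need preference-based utilities — most commonly
EQ-5D-3L index values anchored at 1 (full health) and 0 (dead), with
negative values for states worse than dead. Many oncology studies collect
only the disease-specific EORTC QLQ-C30. *Mapping* (cross-walking)
predicts the utility a patient would have reported on EQ-5D-3L from their
QLQ-C30 responses, so that trials without a generic instrument can still
feed economic models. qolmap implements the full workflow for a
metastatic colorectal cancer setting: instrument scoring, six
mapping-model families with automated model reduction, cross-validated
performance evaluation (including incomplete questionnaires), and a
sensitivity layer quantifying how the choice of utility source moves an
incremental cost-effectiveness ratio (ICER).

Because the underlying trial data are not public, the package pairs the
analysis with a synthetic cohort generator that reproduces the published
marginal structure of the cohort; every pipeline stage is exercised and
tested against that generator.

## Instruments and scoring

`score_qlqc30()` converts the 30 items into 15 scores on 0–100: five
functional scales, global health, and nine symptom scales. With raw score
$RS$ = mean of the answered items and range $r$ (3 for 4-point items, 6
for the two 7-point global items),

- functional scales: $S = (1 - (RS - 1)/r) \cdot 100$ (higher = better),
- symptom scales and global health: $S = ((RS - 1)/r) \cdot 100$
  (higher = worse symptoms / better global health).

A scale is computable when at least half of its items (rounded up) are
answered — the *half-completion rule* — and is missing otherwise. No
imputation is ever performed. Items are coded 1–4 and 1–7; missingness is
`NA`, never zero. `binarize_v3_items()` collapses items 1–5 to the yes/no
coding of questionnaire version 2, which some published algorithms
expect.

`eq5d_utility()` scores a 5-domain, 3-level EQ-5D response with a *value
set*: utility = full-health constant − level decrements − triggered extra
terms (an any-deviation constant and an any-level-3 term). Two published
tariffs ship as JSON data files (Dutch, Lamers et al. 2006; UK MVH/Dolan
1996) with their sources documented in the files; the unit-test suite
deliberately uses only a toy value set so no test depends on those
constants.

## The six mapping families

Let $u_{ij}$ be the utility of patient $i$ at visit $j$ and $x_{ij}$ the
QLQ-C30 predictors.

**Models 1–3 (linear, random intercept).**
$u_{ij} = \beta_0 + x_{ij}'\beta + b_i + \varepsilon_{ij}$ with
$b_i \sim N(0, \sigma_b^2)$. Model 1 uses the 14 functional and symptom
scale scores, model 2 the 30 items as integers, model 3 one dummy per
item level above the reference level 1 (levels unobserved in training are
dropped with a warning, as are aliased columns). Variance components are
estimated by maximum likelihood (lme4); the fixed effects are the implied
GLS estimates. Because several questionnaires come from one patient,
inference uses a cluster-robust sandwich over patients (CR1 small-sample
factor, $t$ statistics on $G-1$ degrees of freedom, $G$ = clusters).
There is no closed-form cluster-robust covariance for mixed models in the
installed toolchain, so the sandwich
$(X'\hat V^{-1}X)^{-1}\big[\sum_g X_g'\hat V_g^{-1}\hat e_g \hat e_g'
\hat V_g^{-1} X_g\big](X'\hat V^{-1}X)^{-1}$
is computed directly with the Woodbury form of
$\hat V_g = \hat\sigma_b^2 J + \hat\sigma_e^2 I$. A plain-OLS fallback
(`use_re = FALSE`) exists because "random effects" and "OLS" are both
defensible estimators for this population-averaged prediction problem;
with a single cluster the fit degenerates to OLS by construction.

**Model 4 (response mapping).** One proportional-odds (ordered logit)
model per EQ-5D domain on the five functional scale scores. In the
level-anchored parameterisation with latent predictor $L$ and threshold
offset $\kappa$:
$$P(\text{level }1) = \frac{1}{1+e^{L}}, \qquad
  P(\text{level}\le 2) = \frac{1}{1+e^{L-\kappa}},$$
and $P(3)$ is the complement. Two scoring modes are provided because the
method's name suggests one and its description the other: `most_likely`
(default; per domain take the argmax level — ties resolve to the better
level — and score the state with a tariff) and `expected` (the
probability-weighted tariff, with the any-deviation/any-level-3 terms
evaluated under independence of domains given the scores). Every output
records its mode; neither is claimed to be the historically intended one.
The modal-level mode inherits a mean bias toward full health whenever
level 1 is modal in every domain, visible in the study replica. A domain
with only two observed levels reduces to logistic regression (single
threshold); a single observed level is an error naming the domain. This
family is tariff-independent until the final scoring step and is exempt
from backward selection, as is the multinomial step of model 6.

**Model 5 (beta regression).** Disutility $d = 1-u$ is compressed into
the open unit interval by $d' = (d(N-1)+0.5)/N$ with $N$ the training
size, then modelled with a logit-link beta regression with constant
precision (mgcv's `betar` family; logit link and constant precision are
the conventional defaults for bounded outcomes). $N$ is stored with the
model so prediction inverts the same transform; predictions therefore lie
strictly below 1 — the family cannot produce negative utilities, which is
acceptable when states worse than dead are rare. Disutilities above 1
(negative utilities) are truncated to 1 before the transform with a
logged count; the source text leaves this step under-specified, and
truncation is the minimal intervention affecting only those rare rows.

**Model 6 (separate equations).** A three-class multinomial logistic
model assigns probabilities to $u < 0.6$ (the region associated with an
extreme-problem response), $0.6 \le u < 1$, and $u = 1$; class-specific
model-1-style linear fits predict within the two non-ceiling classes, and
the prediction is the convex mixture
$\hat u = P(\text{low})\hat u_\text{low} + P(\text{mid})\hat u_\text{mid}
+ P(1)\cdot 1$. An empty class is an error naming the class.

## Backward selection and non-logical coefficients

Families 1–3, 5 and the linear parts of 6 start from the full candidate
set and drop the single least significant term (largest $p > 0.05$; ties
broken by smaller absolute coefficient, then name — the order is not
dictated by the method, so a deterministic rule was chosen) until all
terms satisfy $p \le 0.05$. The intercept is never dropped. In a second
step, surviving coefficients whose sign contradicts the clinical
expectation (functional scales raise utility, symptoms lower it; reversed
on the disutility scale) are removed *simultaneously*, the model is
refit, selection is re-run, and the cycle iterates to a fixed point (at
most 20 rounds). Every removal is logged with its reason (`p_value` or
`sign`), making the reduction auditable. For speed, intermediate
selection refits reuse the variance components of the entering model
(GLS at fixed components equals the profiled ML fixed effects); each
reported model and every pruning round re-estimates the components.

## The synthetic cohort generator

A single latent health trait drives both instruments: patient trait
$T_i \sim N(0, \sigma_b^2)$ (default 1), visit deviation
$N(0, \sigma_w^2)$ (default 0.5²). Each QLQ item cuts
$\pm h_{ij} + \text{noise}$ (item noise SD 1) at equally spaced
thresholds; each EQ-5D domain cuts $-h_{ij} + \text{noise}$ (domain noise
SD 0.7) at thresholds placed by moment matching to the published domain
level frequencies. Per scale, the threshold location and spacing are
solved (1-D root-finding nested in 1-D root-finding, with the scale-score
mean analytic and the SD via quadrature over the trait) so that the
scale-score mean and SD match the published cohort moments exactly in
expectation. The observed utility is the tariff score of the generated
domain levels — never noise added to a latent utility — so rows are
internally consistent by construction.

Consequences of this design, rather than tuned targets: the ceiling mass
at utility 1 is the joint probability of level 1 in all five domains
(roughly 40% at the defaults), utilities are right-skewed, and a small
fraction of deep-tail rows (default 0.2% of rows get a $3\sigma$
latent-trait shift, plus the natural tail) land in states worse than
dead. The defaults were fixed once from the published marginals and the
requirement of a strong cross-instrument correlation; the real
inter-scale correlation matrix was never published, so the generator's
correlation structure is calibrated, not reproduced — a genuine limit on
what passing tests show about real data. Item missingness for the
incomplete records is MCAR at the item level, constrained so every
functional scale keeps at least half its items (no mechanism is described
for the real data; MCAR suffices to exercise the half-rule path).
Visits are spread over patients as evenly as possible so the row count is
exact. A master seed spawns named substreams (cohort, missingness, folds,
PSA, arms) so stages are independently reproducible; equal seeds give
byte-identical output.

`generate_from_linear_model()` and `generate_from_beta_model()` are
parameter-recovery harnesses: covariates are independent truncated
normals on [0, 100] with the published means/SDs (the simplest family
matching the printed moments), utilities follow the supplied coefficient
set plus random intercept and noise, truncated at the ceiling of 1.
Fitting a correctly specified model to their output recovers the
generating coefficients up to the attenuation induced by the ceiling:
with ~3% of rows censored at 1, slope estimates shrink by a few percent —
an inherent property of fitting an uncensored linear model to censored
data, worth remembering when recovery is judged at tight Monte-Carlo
tolerances.

## Validation design

`make_folds()` assigns questionnaires (rows) to folds by default, with
remainder rows going to the lowest-index folds; a patient-level mode
exists because row-level folding lets within-patient correlation leak
between training and test folds (a known limitation of within-sample
validation of panel data). `cross_validate()` re-runs the *entire*
fitting procedure — selection and pruning included — on each training
set. Metrics: mean/SD/min/max of predictions, RMSE, MAE, Spearman
correlation (average ranks), and a t-test of predicted vs observed
(paired by default, since both vectors cover the same rows; an unpaired
flag exists). Per-fold and pooled metrics are both reported rather than
asserting which a given publication used. Zero-variance edge cases
(perfect prediction, constant vectors) report `NA` with a warning instead
of a number. Incomplete questionnaires are evaluated per model on the
rows where every predictor that model retained is computable under the
half rule, with the eligible count reported.

## The cost-effectiveness layer

The original evaluation embedded utilities in a discrete-event
simulation whose structure, transition times and literature utilities are
not reproducible from public text. Since the quantity of interest here is
*how the ICER moves when the utility source changes*, the layer replaces
the simulation with a transparent two-arm algebra:
$\text{QALY}_a = u_a t_a + s_a$, with first-state durations
$t_\text{obs} = 0.65$, $t_\text{trt} = 0.87$ years (ratio 1.33, the
relative person-time of the two arms implied by their observation counts;
the scale puts the reference QALY gain near 0.19) and a fixed
subsequent-state contribution $s$ = 0.8 per arm. Incremental cost is
fixed at EUR 30,163. The probabilistic analysis draws each arm's utility
from its method-of-moments beta distribution
($\nu = m(1-m)/se^2 - 1$, shapes $(m\nu, (1-m)\nu)$; a zero SE
degenerates to the mean), uses 10,000 samples, common random numbers
across sources (so identical sources tie exactly and source differences
are estimated with reduced Monte-Carlo variance), a point ICER from cloud
means (stable near the dominance boundary, unlike the mean of ratios),
and a 2.5/97.5 percentile interval. Negative utilities are outside the
beta support by design; arm means near the ceiling remain inside (0, 1).

## Numerical choices and degenerate inputs

- Selection treats `NA` p-values (zero-residual fits) as "keep".
- Quadrature for the generator calibration: 241-point grid over ±6 SD;
  threshold solving tolerance 1e-8 to 1e-10; infeasible moment targets
  raise a configuration error rather than silently clamping far off.
- Round-trip identities (open-interval transform, method-of-moments
  shapes, serialisation) hold to 1e-12 and are tested at that tolerance.
- Coefficient files store full precision; exported tables round to 3
  decimals (whole EUR for ICERs).
- Reports are byte-reproducible under a fixed seed; wall-clock
  timestamps are therefore confined to console logging and never enter
  report files.

Problem sizes in the test suite mirror the study (1905 rows, 473
patients, 5 folds, 120 incomplete records) for the end-to-end and
recovery checks, with smaller cohorts (~300–800 rows) for unit-level
model behaviour.

## Known limitations

- All validation is within-sample in the cross-validation sense; nothing
  here substitutes for external validation on an independent cohort.
- The generator matches marginal moments and induces a plausible —
  not estimated — dependence structure; absolute performance numbers on
  synthetic data (RMSE ≈ 0.1, Spearman ≈ 0.8 at the defaults) should not
  be read as predictions for any real dataset.
- The most-likely response-mapping mode overstates mean utility when
  level 1 dominates; the expected mode avoids this but is no longer a
  single health state.
- Linear families predict outside [min, 1] by design (documented, not
  clipped); the beta family cannot reach 1 or negative values.
- The CEA layer preserves the sensitivity question, not the absolute
  ICERs of any published simulation.
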