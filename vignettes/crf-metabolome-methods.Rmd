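---
title: "Methods: sex-stratified association of cardiorespiratory fitness with the plasma metabolome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified association of cardiorespiratory fitness with the plasma metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crfmet)
```

# The analysis problem

Cardiorespiratory fitness (CRF), measured as peak oxygen uptake during an
incremental exercise test (VO2peak, mL·kg⁻¹·min⁻¹), is a strong predictor of
all-cause mortality. `crfmet` implements a pipeline for asking, in a
cross-sectional cohort profiled on several metabolomics platforms, three
questions per sex:

1. **Bivariate:** which single plasma analytes correlate with VO2peak after
   removing the effects of age (and menopausal status in females), and which
   of those correlations survive adjustment for 21 additional phenotypical
   and clinical covariates?
2. **Multivariate:** which analytes contribute consistently to a
   partial-least-squares (PLS) model of VO2peak on all analytes jointly, as
   judged by a rank-product permutation test?
3. **Explanatory:** which small sets of covariates and analytes, chosen by
   repeated cross-validated stepwise regression, explain VO2peak best?

Everything is sex-stratified: fitness, body composition and the metabolome
all differ systematically between the sexes, and pooling would confound
those differences with the associations of interest.

# Data model and preprocessing

A `metabolite_matrix` holds a complete samples-by-analytes grid in which each
cell is *detected* (a nonnegative intensity), *below the limit of detection*
(below-LOD: the analyte is present but unquantifiable), or *missing* (no
measurement). The distinction matters: below-LOD cells carry the information
"low", so they are retained through the rank transform as a block tied at the
minimum rank, while missing cells propagate as missing. Detection frequency
counts only detected cells by default (below-LOD counts as not detected);
both choices are arguments, since conventions differ between laboratories.

Matrix integration applies two filters, in this order:

* **Cross-platform duplicates.** When the same chemical species is measured
  on several platforms, only the copy from the most quantitative method is
  kept (smallest `quantitative_rank`; ties broken by platform order, then
  analyte id, so the outcome is deterministic).
* **Detection frequency.** An analyte must be detected in at least 20% of
  the female *and* of the male subgroup; failing either removes it.

Each step returns a report (counts in/out, removed ids), and the pipeline
asserts the conservation identity `kept + removed = input` so no analyte can
silently vanish.

## Van der Waerden scores

All variables — analytes, VO2peak, and the covariates — are transformed to
Van der Waerden (rank-based inverse normal) scores before any statistic is
computed: values are ranked (average ranks on ties), rescaled to
rank/(n+1), and mapped through the standard normal quantile function. The
n+1 denominator keeps the extreme quantiles finite; scores are computed per
sex-stratified subsample because every downstream statistic is sex-specific.
The transform is monotone and idempotent, and puts all platforms on one
scale. A fully tied vector yields all-zero scores (or an error under
`strict = TRUE`).

## Confounder adjustment

"Adjusted for" is read as ordinary least-squares residualization on an
intercept plus the confounder scores (age score; plus a 0/1 post-menopause
indicator in females). Residuals are mean-zero and orthogonal to every
covariate by construction, and `residualize()` refuses rank-deficient
covariate sets, naming the collinear columns.

One genuinely open design point is *where* the adjustment happens for the
multivariate stage: inside every cross-validation fold (refit on each
calibration set) or once on the full per-sex sample. This package adjusts
**once, before the outer loop**, for a consistency reason: the permutation
null permutes the adjusted response, so computing the observed statistic
under a different (within-fold) adjustment would compare observed and null
rank products on different footings. Unit-variance scaling of the
predictors, by contrast, is always recomputed from each calibration split.

## Imputation of AEE and PWV

Activity energy expenditure and pulse-wave velocity are the two covariates
allowed to be missing. They are imputed by a random forest (500 trees,
single pass, `ranger`) trained on the complete cases with sex, age and the
remaining covariates as predictors. Forest predictions are averages of
observed leaves, so imputed values always lie within the observed range. A
single pass (rather than an iterative scheme) is used because missingness is
confined to two columns at a low rate; the tree count and seed are
arguments, and the imputation is deterministic given the seed.

# Bivariate stage

For each analyte, `partial_correlation()` computes the Pearson correlation
of the residuals of analyte and response on the same covariate set, with a
95% Fisher-z confidence interval,

$$\tanh\!\left(\operatorname{atanh}(r) \pm \frac{1.96}{\sqrt{n-3}}\right),$$

and flags the association significant exactly when the interval excludes
zero. Two points deserve emphasis:

* The standard error uses `n − 3` with **no degrees-of-freedom correction**
  for the covariates. This convention was validated against two published
  interval endpoints (r = 0.37, n = 102 → (0.19, 0.53); r = −0.25,
  n = 150 → (−0.39, −0.09)), which decide between the candidate conventions.
* Significance is exclusively CI-based; there is **no multiple-testing
  control** anywhere in the bivariate stage. That mirrors the analysis
  design this package implements, and users should treat per-analyte flags
  as exploratory. Under a global null, about 5% of analytes will be flagged
  — the test suite verifies this rate.

Two adjustment profiles are standard: `*` (confounders only) and `**`
(confounders plus all 21 covariates, residualized jointly). Analytes whose
association with fitness is mediated by body composition are significant
under `*` and drop out under `**`; the synthetic generator plants such
analytes, and the suite checks that the attenuation is detected.

# Multivariate stage: PLS rank products

Single-response NIPALS PLS is fit on column-standardized analytes (means
and scales from the calibration data only). The procedure:

* **Outer loop** — 20 random 80/20 calibration/test splits. Per split, the
  number of latent components (1–10) is tuned by a single random eight-fold
  cross-validation on the calibration set, minimizing RMSE (smallest count
  on ties); the model is refit at the tuned count and each analyte is ranked
  by the negative absolute value of its regression coefficient (rank 1 =
  largest, average ranks on ties, so each split's ranks sum to p(p+1)/2).
* **Rank product** — the geometric mean of an analyte's ranks across splits;
  consistently important analytes have small rank products.
* **Permutation test** — the adjusted response is permuted (2500 times at
  full scale); the permutation frequency of an analyte is the fraction of
  permutations whose rank product falls *strictly below* the observed one
  (ties count as not below, per the "below" criterion). Frequencies at or
  below 0.05 are significant. The mean test RMSE of every permutation is
  retained so the overall model's relevance can be checked: when permuted
  RMSEs are not higher than the observed one, the multivariate association
  as a whole carries no information.

Two permutation modes are provided because the faithful variant is
expensive: `full_refit` re-runs the entire outer procedure (including
tuning) per permutation; `fast_reuse` keeps the outer splits and tuned
component counts and refits only the PLS coefficients. The two agree on
significance calls in ≥ 90% of planted-signal simulations in the test
suite, and `fast_reuse` is the default. Whether components should be
re-tuned under the null is genuinely unspecified in this design; neither
mode is claimed as canonical.

Numerical notes: NIPALS stops early when a weight or score norm falls below
1e-12 (rank exhaustion), truncating with a warning; zero-variance columns
are an error (they cannot occur after the rank transform on untied data);
the PLS solution at full component count equals the least-squares solution,
which the tests verify against both `lm.fit` and `mixOmics::pls`.

# Explanatory stage: cross-validated stepwise selection

Forward selection maximizes in-sample R² greedily (ties by variable id,
collinear candidates skipped and logged) — there is no p-to-enter and no
backward step. Selection stability is assessed by repeating, 1000 times at
full scale: draw a random 80/20 split, select forward on the calibration
set, and after each entered variable evaluate test-set RMSE; stop the first
time the RMSE increases, *excluding* the degrading variable. "Predictive
accuracy" is operationalized as test RMSE, which on a fixed test set is
monotone-equivalent to test R². A variable's selection frequency is the
fraction of repeats in which it was kept; all variables at frequency
≥ 0.05 enter a final least-squares model on all samples, reported with R²
and adjusted R² = 1 − (1 − R²)(n − 1)/(n − p − 1).

Three wirings are standard: approach 1 selects among the 21 covariates
only; approach 2 fixes all 21 covariates in the model and selects among
analytes; approach 3 lets covariates and analytes compete. In approach 2
the test-RMSE evaluation starts after the fixed block is fitted, so the
stop rule judges only the metabolite steps. All variables, response
included, are pre-adjusted for the confounders before any selection.

The forward engine is implemented by incremental Gram–Schmidt
orthogonalization: after a variable enters, the response residual and all
remaining candidates are orthogonalized against it, so each step costs
O(np) and is algebraically exact greedy R² maximization.

# Cohort descriptives

Participants are grouped into sex-specific VO2peak quartiles (type-7 sample
quantiles; a value exactly on a boundary falls into the lower quarter — the
convention is stated because quantile definitions differ). Numeric
characteristics are compared across quarters by Welch's heteroscedastic
ANOVA with Satterthwaite degrees of freedom; categorical ones (menopausal
status) by Pearson's chi-squared without continuity correction, with a
warning when an expected cell is below 5. Relative means use the lowest
quarter as reference. Covariates are imputed *before* the quarter summaries,
so the per-variable sample sizes are constant; a source analysis that
tabulated pre-imputation data would show reduced n for AEE/PWV instead.

# The synthetic cohort generator

No public cohort accompanies this analysis design, so the generator is the
test bed, and its defaults are the study conditions:

* 102 females, 150 males; age uniform on 18–80; menopause in females via a
  logistic threshold at age 50 (scale 2.5 years).
* VO2peak = sex intercept (34.3 F / 42.0 M at age 49) − 0.45·(age − 49)
  − b·(FM% − mean) + Gaussian noise, with b = 0.7/0.9 (F/M) and noise SD
  5.92/5.78 against fat-mass SDs of 6/5.5. These four numbers make fat-mass
  percentage explain ≈ 33.5% (F) / 42.3% (M) of the age-adjusted VO2peak
  variance and give a pooled mean ≈ 38.9 and SD ≈ 11.7 mL·kg⁻¹·min⁻¹.
* The 21 covariates are linear combinations of the age score, the fat-mass
  component and the adjusted fitness signal plus noise, with loadings set so
  their induced adjusted correlations with VO2peak sit near the published
  sex-specific values (HDL ≈ +0.4, VATM ≈ −0.5, PWV ≈ −0.35, TGs ≈ −0.3,
  HR_rest ≈ −0.3, AEE ≈ +0.2) while fat mass remains the single dominant
  determinant — the condition that makes it enter every stepwise model
  first.
* Analytes come in blocks: female-specific, male-specific and shared blocks
  load on the standardized adjusted fitness signal with planted partial
  correlations drawn from ±(0.2–0.4); a confounder-only block loads on age;
  a covariate-mediated block loads on the fat-mass component (loading 0.55,
  inducing |r| ≈ 0.33 that vanishes under the fully adjusted profile); the
  rest are null. Effects are planted on the adjusted scale and raw
  intensities reconstructed through a log-normal marginal, so the planted
  correlations are recovered in expectation after the rank transform.
* Realism features: per-analyte below-LOD censoring at a random quantile
  ≤ 10%, cross-platform duplicate copies (shared latent value plus platform
  noise, less quantitative rank), and sporadic missing AEE/PWV (5%).

What the generator does **not** emulate: real metabolite covariance
structure (analytes are conditionally independent given the planted
factors), platform drift and batch effects, non-Gaussian tails beyond the
log-normal marginal, or any particular cohort's distributions beyond the
anchors above. Passing tests therefore demonstrate that the statistical
machinery has its stated operating characteristics (type-I error, power
against planted effects, attenuation of mediated effects), not that any
real-data finding is reproduced.

`p_analytes` defaults to 120 rather than the full 427 of the motivating
design so the complete pipeline runs in minutes on one core; every block
size scales through the configuration.

# Problem sizes and determinism

The packaged defaults for exploratory runs are 200 permutations and the
outer/inner loop sizes above; the test suite uses 20–200 permutations,
60–200 analytes, and 100–1000 stepwise repeats depending on the property
under test — sizes chosen so each suite completes in seconds to a few
minutes while keeping binomial confidence bands tight enough to be
meaningful (rates are always checked within three binomial standard
errors). Full-scale settings (2500 permutations, 1000 repeats, 427
analytes) are plain configuration changes.

Every stochastic stage takes a seed and derives per-split and
per-permutation substreams from it, so any single split or permutation can
be reproduced in isolation; the whole pipeline is bit-identical under a
fixed (input, configuration, seed) triple, which the suite asserts by
re-running it.

# Known limitations

* No multiplicity control in the bivariate stage (by design, see above).
* The Fisher-z interval ignores the degrees of freedom consumed by
  covariates; for 21 covariates and n ≈ 100 the intervals are slightly
  narrower than a corrected version would be.
* `fast_reuse` underestimates the variability contributed by component
  re-tuning under the null; use `full_refit` for confirmatory runs.
* Stepwise selection inherits all the known instabilities of greedy
  forward search; the frequency thresholding mitigates but does not remove
  them, and no post-selection inference is offered.
* Below-LOD handling assumes the censoring is at the low end; analytes
  censored from above would need a different tie block.
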