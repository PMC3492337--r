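---
title: "Latent class subtyping of nonischemic HFREF: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class subtyping of nonischemic HFREF: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfsubtype)
```

## The problem

Heart failure with reduced ejection fraction (HFREF) is clinically
heterogeneous: patients who share the label differ in etiology, prognosis,
and response to therapy. In nonischemic HFREF there is no reliable way to
predict who will respond to a beta-blocker. `hfsubtype` implements a
subtype-discovery pipeline for randomized-trial cohorts of nonischemic
HFREF patients (the motivating population is the bucindolol-vs-placebo
BEST trial, NYHA III–IV, LVEF $\le 35\%$): patients are phenotyped on 27
discretized clinical features, latent class analysis identifies prevalent
clinical profiles, and subtype membership is related to mortality, LVEF
response, and treatment effect, in comparison and combination with the
Seattle Heart Failure Model (SHFM) score.

Two latent class models are fit to disjoint-but-overlapping variable sets:

* **LCM A** (16 variables) collects features plausibly related to the
  *pathogenesis* of HFREF: age of HF onset, sex, race, body mass index,
  diabetes grade, blood-pressure stage, total cholesterol, triglycerides,
  creatinine clearance, hematocrit, atrial fibrillation, left bundle
  branch block, pacemaker, mitral and aortic valve disease, and history of
  sudden cardiac death.
* **LCM B** (14 variables) collects markers of *progression and
  severity*: age, LVEF, RVEF, QRS duration, heart rate, systolic blood
  pressure, pulse pressure, jugular venous distension, blood urea
  nitrogen, alanine aminotransferase, serum sodium, plus body mass index,
  creatinine clearance and hematocrit.

Body mass index, creatinine clearance and hematocrit appear in both sets
— the same measurement can mark cause or consequence depending on
context. The categorical response-pattern spaces are enormous
(`r format(pattern_space_size(default_codebook(), "A"), big.mark = ",")`
patterns for LCM A and
`r format(pattern_space_size(default_codebook(), "B"), big.mark = ",")`
for LCM B), which is exactly why a saturated interaction analysis is
impossible at trial sample sizes and a latent class aggregation is used.

## The model

A $K$-class polytomous latent class model assumes each subject belongs to
an unobserved class $Z_i \in \{1,\dots,K\}$ with prevalences $\pi_k$, and
that the $J$ categorical indicators are independent given class (local
independence):

$$P(Y_i = y) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J} p_{jk}(y_j),$$

where $p_{jk}(\ell)$ is the probability that variable $j$ takes level
$\ell$ in class $k$. Estimation is maximum likelihood by EM
(`fit_lca()`), with the E-step computing posterior memberships by Bayes'
rule and the M-step replacing prevalences and conditionals by
posterior-weighted frequencies. The number of free parameters is
$(K-1) + K\sum_j (L_j - 1)$.

Numerical choices:

* **Initialisation**: posterior rows drawn from a symmetric Dirichlet(1),
  followed by an M-step; `n_starts` independent restarts (default 20, 10
  in the selection protocol), best likelihood kept. Deterministic given
  `seed`.
* **Convergence**: relative log-likelihood change below `1e-8`, capped at
  5000 iterations; non-convergence is flagged, never silently accepted.
  The EM trace is recorded and monotonicity asserted.
* **Probability floor**: conditionals are floored at `1e-10` in the
  M-step (then renormalised) so no observed pattern can get exactly zero
  mass; floor hits are counted in the fit object. Several reference
  profiles contain structural zeros (e.g. the all-male class), so the
  floor binds routinely and harmlessly.
* **Label order**: classes are relabelled by descending prevalence. Class
  numbering is not identifiable in a mixture, so comparisons against any
  external labelling must be made after best-permutation matching.
* **Missing data**: listwise deletion within each LCM's variable set;
  `n_used` is recorded and may differ between the two models. Subtype
  assignment of new subjects (`assign_subtype()`) refuses partial
  profiles rather than guessing.

## Model-order selection

`select_num_classes()` scans $K = 2,\dots,10$ and applies a two-stage
rule: find the first local minimum of BIC
($-2\ell + \Phi\log n$), then select the first $K$ at or beyond it that
is a local minimum of the Pearson chi-square statistic over response
patterns,

$$X^2 = \sum_{\text{observed patterns}} \frac{(O - E)^2}{E} \;+\;
  \Big(n - \sum_{\text{observed}} E\Big),$$

with $E = n\,\hat P(\text{pattern})$ and the second term a residual cell
aggregating all unobserved patterns. "Local minimum" uses strict
comparisons, one-sided at scan endpoints (including the left endpoint of
the restricted chi-square scan, so $K_{\mathrm{BIC}}$ itself is selected
whenever $X^2(K_{\mathrm{BIC}}) < X^2(K_{\mathrm{BIC}}+1)$). If a stage
has no local minimum, the global minimum over the admissible range is
used and flagged in the diagnostics table, which is always returned for
audit.

### What the selection rule does and does not do

This package's own simulations (reproduced by the test suite and the
acceptance script) show that on cohorts of $n = 1121$ drawn from the
bundled 6-class (LCM A) and 5-class (LCM B) reference structures:

* parameter recovery at fixed true $K$ is excellent at large $n$
  (max-abs conditional-probability error $< 0.05$ at $n = 20{,}000$);
* the BIC stage under-selects at $n = 1121$ (first local minimum at 5–6
  for LCM A, 3–4 for LCM B) even when EM is run to the global optimum,
  and concentrates on the generating counts (6 and 5) at $n = 5000$;
* the chi-square refinement is unreliable in this regime. With hundreds
  of millions of possible patterns, nearly every observed pattern is a
  singleton and $X^2 \approx \sum_i 1/(n \hat P(y_i))$ is dominated by
  the few worst-fit patterns. Each class added beyond the truth can park
  a tiny class on those patterns, so $X^2$ keeps falling past the true
  $K$ and the "first local minimum" halts on sampling noise. The
  chi-square of the *true* generating model is no lower than that of
  overfit solutions. Selections therefore spread over 6–10 (LCM A) and
  3–8 (LCM B) across seeds, and sharpening the class-conditionals does
  not repair this.

The rule is implemented exactly as published because reproducing the
procedure is the point; users choosing a class count for new analyses
should read the full diagnostics table (and weigh BIC at realistic
sample sizes) rather than trusting the chi-square refinement blindly.

## Bayesian subtype assignment

A frozen model assigns any encoded subject posterior class probabilities
proportional to $\pi_k \prod_j p_{jk}(y_{j})$; the hard label is the
posterior argmax with ties broken toward the lower class index. This is
how external cohorts are classified without refitting
(`apply_frozen_models()`).

## The codebook

`default_codebook()` encodes the 27 features with the printed level sets.
Conventions the tables leave open:

* **Bin edges**: intervals are lower-closed/upper-open, the last closed
  above, so BMI 25 falls in "25–30" and hematocrit 40 in ">40". This
  makes encoding total and deterministic on all finite inputs.
* **Blood-pressure composite** (LCM A): systolic and diastolic are staged
  separately ($<120/80$, $120{-}140/80{-}90$, $140{-}160/90{-}100$,
  $>160/100$) and the category is the maximum of the two component
  stages, the usual clinical staging convention.
* **Flags** (AF, LBBB, pacemaker, valve disease, sudden-death history):
  present/absent, absence of a record meaning absent.
* One printed systolic-pressure row label ("90–110") is treated as
  "90–100": bins must partition the axis and the adjacent rows are
  100–110 and <90.

## SHFM scoring

The SHFM is a published proportional-hazards risk score; its linear
predictor combines male sex, age/10, NYHA class, 100/LVEF, systolic
pressure/10, (138 − sodium), 100/cholesterol, |16 − hemoglobin|, percent
lymphocytes, uric acid, diuretic dose, etiology, and medication/device
flags, with one score unit worth roughly a hazard ratio of $e$. The exact
published coefficients are not redistributable here, so
`shfm_default_coefficients()` ships a clearly versioned **synthetic**
stand-in (version `synthetic-1.0`): correct transforms and signs,
plausible magnitudes, intercept and baseline one-year survival calibrated
so a typical NYHA III patient scores near 0 with ~10% predicted one-year
mortality. Every analysis here depends only on structural properties —
linearity, the exact beta-blocker coefficient toggle (scores with and
without it are both produced; the without-version is used for
treatment-effect analyses), and the percent-lymphocytes = 25 imputation
when the measurement is absent. Users with access to the published
coefficients can drop them in via `read_shfm_coefficients()`.

## Outcome models

* `lvef_response()`: improvement $\ge 5$ LVEF points with month-12 LVEF
  $\ge 35\%$; missing month-12 gives a missing indicator.
* `two_by_two_odds_ratio()`: cross-product OR with Woolf (log) intervals;
  0.5 continuity correction when a cell is zero (flagged).
* `fit_ph_model()`: Cox partial likelihood, Efron ties (less biased than
  Breslow with tied days), treatment × subtype interactions giving
  per-subtype hazard ratios via contrasts; log-rank statistic across
  subtypes; strata without events excluded with a warning.
* `test_ph_assumption()`: scaled Schoenfeld correlation test, flag at
  p < 0.05 (conventional).
* `add_time_interaction()`: flagged covariates get an
  $x \cdot \log t$ time-varying effect, so
  $\mathrm{HR}(t) = \exp(\beta + \gamma \log t)$; with time in years the
  main effect is the hazard ratio at one year, and HRs are reported at
  1/2/3 years and the geometric mean of event times. The log-time basis
  is chosen because smoothly rising or falling HR sequences anchored at a
  geometric-mean time are exactly what a log-linear effect produces.
* `km_curve()`: product-limit estimates with Greenwood standard errors.

## Model evaluation

Seven predictor combinations (SHFM, LCM A, LCM B, A+B, SHFM+A, SHFM+B,
All; randomized arm always included) are evaluated for three outcomes
(cumulative mortality via Cox; one-year mortality and LVEF response via
logistic regression) with:

* `harrell_c()` for censored survival (pairs usable when the earlier time
  is an event; risk ties 0.5) and `binary_c()` (Mann–Whitney AUC);
* `compare_c()`, a DeLong-type paired test, squared standardized
  difference referred to $\chi^2_1$;
* `nri()`, categorical net reclassification improvement over configurable
  risk categories plus the category-free version. Because the original
  category cut points are not published, defaults are 5%/15% for one-year
  mortality and 20%/40% for LVEF response, and the category-free NRI is
  always reported alongside so conclusions never hinge on the unprinted
  choice;
* `loocv_c()`, deterministic leave-one-out cross-validation of the
  regression stage with upstream subtype assignments and SHFM scores
  frozen (refitting the LCA inside every fold is a pipeline option, not
  the default: it is far costlier and the published validation scheme is
  agnostic). Note the textbook LOOCV artifact: an intercept-only model's
  out-of-fold predictions are perfectly anti-ordered with the outcome,
  giving c = 0, not 0.5; informative models are unaffected.

## The synthetic cohort generator

No individual-level trial data are distributable, so
`generate_cohort()` emulates a BEST-like nonischemic cohort and is the
package's test bed. The stated world:

* $n = 1121$, 563 placebo / 558 bucindolol;
* LCM A: 6 classes with prevalences 18.6/14.4/16.6/14.5/7.8/28.3%
  (renormalised); LCM B: 5 classes, 22.6/33.8/23.0/11.7/8.9%;
  class-conditional category frequencies transcribed from the published
  within-subtype percentage profiles, each column renormalised;
* features drawn independently given class (matching the model's own
  local-independence assumption; no residual correlation is injected);
* numeric features decoded to bin midpoints, open-ended bins to the edge
  ± 10% of the adjacent bin width, so re-encoding reproduces the
  generated categories exactly;
* outcomes per class × arm from the published outcome table: death times
  piecewise-exponential with the [0,1y] hazard solved to match one-year
  mortality and the (1y,3y] hazard solved to match cumulative mortality
  at 3 years (the late hazard continues beyond); administrative censoring
  uniform on 2–4 years, so one-year vital status is always observed;
  LVEF response Bernoulli, independent of survival given class and arm
  (only marginal rates are published), with month-12 LVEF values
  constructed to satisfy or violate the response definition.

What it does **not** emulate — and therefore what a green test does not
establish: real within-class correlation structure, measurement error and
real missingness, the joint law of survival and LVEF response, the true
follow-up distribution, and (critically) the *fitted* subtype-conditional
probabilities, for which the published within-subtype frequencies are
only stand-ins. In `which = "both"` cohorts the two class labels are
drawn independently, shared variables and blood pressures follow the LCM
A draw, and the B-side systolic/pulse-pressure categories derive from
those raw values, so single-LCM cohorts (`which = "A"` / `"B"`) are the
right input for per-model recovery studies.

## Design choices that were genuinely open

* Count reconstruction from printed percentages uses round-half-up; this
  reproduces all six published odds ratios to two decimals and is a
  fixture convention, not a claim about the trial's raw counts.
* The modal selected K over seeded replicates resolves ties to the
  smaller count (parsimony).
* The B-only cohort derives diastolic pressure as systolic minus pulse
  pressure so the raw schema stays internally consistent.
* Whether per-subtype treatment effects come from one interaction model
  or stratified per-subtype fits is ambiguous in the source; both are
  provided (`fit_ph_model(..., subtype=)` contrasts vs the per-subtype
  fits inside `subtype_outcome_table()`), and they agree when no
  covariates are shared.
* Hypertension-type staging uses measured randomization blood pressure,
  not history.

## Known limitations

The model-order acceptance targets (modal selected K = 6 for LCM A and 5
for LCM B at n = 1121) are **not met** by this implementation of the
published rule on the stated synthetic world; the mechanism is analysed
above and quantified by the test suite and `scripts/acceptance.R`. All
other pipeline stages meet their stated checks. External validation is
structural only: applying frozen models to a second cohort is supported
and tested on exchangeable synthetic cohorts, but no claim is made about
any real validation population.
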