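---
title: "Modelling attrition bias in cohorts of older people"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling attrition bias in cohorts of older people}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortdrift)
```

## The problem

A longitudinal study of older people loses participants in two
fundamentally different ways. Death removes individuals from the study
cohort *and* from the target population the study generalizes to. Every
other form of attrition — withdrawal, withdrawal due to frailty, loss to
follow up — removes individuals from the cohort only. When a risk factor
is differentially associated with either process, the prevalence of that
factor in the remaining cohort drifts away from (or towards) its
prevalence in the population, and estimates computed from the survivors
stop being representative. `cohortdrift` provides (i) a deterministic
model of that drift, (ii) a synthetic generator of multi-wave cohorts
with the attrition structure of a real national cohort of women born
1921–26, (iii) the multinomial logistic attrition analysis applied to
such cohorts, and (iv) survey-weighted prevalence comparison against
external population series.

## The prevalence recursions

Consider a risk factor that is fixed at the individual level (country of
birth is the canonical example). Write $p$ for its prevalence, $I$ for
the per-step incidence of an attrition event among the *unexposed*, and
$RR$ for the relative risk of that event among the exposed. Over one time
step the exposed mass $p$ shrinks by the factor $1 - RR \cdot I$ and the
unexposed mass $1-p$ by $1 - I$; prevalence at the next step is the
exposed share of the survivors. For the population (death only):

$$p' \;=\; \frac{A}{(1-p)(1-I_{pd}) + A}, \qquad
  A = p\,\bigl[1 - RR_{pd} I_{pd}\bigr]$$

and for the cohort, which loses members to death and non-death attrition
independently within a step:

$$p' \;=\; \frac{B}{(1-p)(1-I_{cd})(1-I_{ca}) + B}, \qquad
  B = p\,\bigl[1 - RR_{cd} I_{cd}\bigr]\bigl[1 - RR_{ca} I_{ca}\bigr].$$

Bias is stored **signed** as $p_{pop} - p_{cohort}$: positive when the
cohort under-represents the factor. A time step is abstract — any period
for which the incidences hold.

Two structural facts anchor the implementation and are enforced by
tests:

* $RR = 1$ makes the update an exact fixed point (non-differential
  attrition never changes composition), and
* each update equals the explicit two-bucket survivor count to
  $10^{-12}$, which is the independent oracle used throughout the test
  suite.

`canonical_scenarios()` returns the standard 2×4 grid: association with
death (shared by population and cohort), with non-death attrition, with
both, or with neither, each started either without initial bias
($p_{c,0} = p_{p,0} = 0.25$) or with the cohort at $0.20$; all
incidences are $0.10$ per step, an association means $RR = 2$, and the
horizon is 10 steps. The qualitative behaviour is: nothing moves without
an association; a shared mortality association erodes an initial bias
(convergence) while prevalence is below one half — and *inflates* it
when prevalence exceeds one half in both groups, since the exposed then
form the majority being depleted; a non-death association moves the
cohort alone, so bias grows without bound in step count; with both, the
cohort outruns the population and bias grows from any starting point.
These are exactly the checks in `test-bias-model.R`.

Degenerate extinction (a denominator of zero, reachable only when
$p = 1$ and $RR \cdot I = 1$) raises an error rather than returning a
convention value: prevalence among zero survivors is undefined.
$RR \cdot I > 1$ is rejected at construction, never clamped.

## What the synthetic generator emulates

No individual-level data from the emulated study are shipped or used.
The generator reproduces the *published statistical structure* of the
1921–26 cohort (12 432 women at the 1996 baseline, five surveys to
2008):

* **Baseline marginals** — seven categorical risk factors (country of
  birth, highest qualification, BMI class, physical activity, alcohol,
  smoking, self-reported health) drawn independently from their
  published complete-case shares (`alswh_baseline_specs()`). Only
  marginals are published, so independence is the default joint
  distribution; a dependence structure can be injected by transforming
  the baseline table before status assignment. Recovery tests only
  require the marginal/coefficient structure, so this loses nothing
  they can detect.
* **Final status** — Survey-5 attrition status (respondent, dead,
  frail, withdrawn, lost) is drawn per woman from a multinomial logit
  whose log odds ratios are the published values
  (`alswh_coefficients()`) and whose intercepts are calibrated by
  `calibrate_intercepts()` so that the *exact* expected marginals over
  the 3 600-cell baseline distribution equal the published Survey-5
  shares (44.7 / 28.4 / 5.1 / 11.4 / 10.4 %). Calibration is an
  iterative proportional-fitting update (shift each intercept by the
  log target/achieved ratio), converging below $10^{-6}$ in ~30
  iterations; with no covariates it reduces to the closed form
  $\log(t_k / t_{respondent})$. Drawing the final status directly
  mirrors what the analysis model fits — cumulative status, not
  wave-specific hazards.
* **Wave pattern** — `survey_transition_rates()` converts the published
  cumulative five-category table at Surveys 2–5 into per-interval
  conditional hazards, treating all four non-respondent states as
  absorbing. The published rows are renormalized (one row sums to
  100.1 % as printed), and the one non-monotone column — lost to follow
  up dips from 9.0 % to 8.7 % between Surveys 3 and 4, because the real
  study lets lost women return — is clamped to a zero increment. The
  achieved cumulative table therefore deviates from the printed one at
  Survey 4 only (lost 9.0 % vs 8.7 %); Survey-5 targets are hit
  exactly in expectation. When a final status already exists,
  `expand_to_surveys()` draws only the *timing* of exit, proportional
  to the unconditional per-interval entry mass, so the covariate-linked
  Survey-5 distribution is untouched.
* **Missingness** — item non-response is imposed completely at random
  at the published per-variable rates (BMI 11.0 %, smoking 7.4 %,
  country of birth 7.0 %). The missingness mechanism of the real study
  is uncharacterized; MCAR is the only defensible default. The
  remaining four factors are given 1.6 % each, chosen once so the
  expected complete-case fraction equals the published 71.9 %
  (8 938 / 12 432) under independence.
* **Weights** — three area strata (city / rural / remote) with
  population shares 0.64 / 0.26 / 0.10 and rural and remote sampled at
  twice the city rate, matching the study's stated design of
  intentional over-sampling of rural and remote women (the published
  account states the fact, not the factor; 2× is the study's documented
  design choice). Weights are inverse sampling factors normalized to
  mean 1, so weighted stratum shares estimate population shares.

What the generator does **not** emulate: dependence between risk
factors, informative (MNAR) missingness, return from loss to follow up,
wave-specific covariate effects, recruitment and linkage mechanics, and
sampling-frame idiosyncrasies. Passing recovery tests therefore shows
that the *analysis pipeline is correct under the published generative
structure* — not that real data meet that structure.

## The attrition analysis

`attrition_table()` tabulates the five categories per survey against the
initial denominator. `fit_attrition_model()` fits the five-outcome
multinomial logit with `respondent` as the reference outcome via
`nnet::multinom`, with each factor releveled to its reference category:
modal category for nominal factors, declared best-survival end category
for ordinal ones (Excellent for self-reported health, low-risk drinker
for alcohol, university for education — substantive declarations, not
data-driven). Confidence intervals are Wald intervals on the log-odds
scale; a category is "significant" when its interval excludes 1. Empty
factor-by-outcome cells are a named error before fitting, since they
produce separation.

`univariate_screen()` implements the two-stage retention rule: keep
factors significant on their own, then drop factors with no significant
category from the joint model. The published procedure describes a
single pass; the implementation iterates to a fixed point (at most 10
rounds, each drop recorded) because a single pass can leave factors
that lose significance once others are removed. On a 2-outcome collapse
with one binary factor the fitted OR equals the closed-form
contingency-table OR (ad/bc) to $10^{-8}$ — the dual-route check that
the optimizer, not the bookkeeping, produces the estimates.

A note on null behaviour: with no planted associations at $n = 50\,000$,
Wald intervals exclude 1 for about 5 % of categories, as they should.
For the sparsest cells (3 % categories × the 5 % frailty outcome) the
standard error of a log OR is ≈ 0.13, so individual null ORs of 1.2–1.3
are routine; "near 1" is a statement about the ensemble, and the tests
phrase it that way.

## Population comparison

`dichotomize()` collapses factors by explicit positive sets (the two
published rules — non-English-speaking country of birth, current-or-ex
smoking — are in `dichotomy_rules()`); `weighted_prevalence()` is
$\sum w x / \sum w$ over non-missing records, invariant to weight
rescaling; `bias_series()` aligns a cohort series with an external
population series on *identical* time labels (an explicit `time_map`
reconciles calendars like 1995/6 vs 1996 — never fuzzy matching) and
reports signed bias with direction labels. Published magnitudes are
reproduced exactly from the published prevalence pairs:
under-representation of non-English-speaking birth growing 0.039 →
0.069 → 0.072 across the three censuses, over-representation of
current-or-ex smoking growing 0.026 → 0.058 between the two health
surveys. Whether a real cohort's wave prevalences should use baseline
or wave-specific factor values is ambiguous for mutable factors;
`cohort_prevalence_by_survey()` uses baseline values, consistent with
the fixed-factor assumption of the drift model.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use $n = 50\,000$ for
parameter recovery (about 5.5× the published complete-case sample, so
every planted coefficient sits comfortably inside its published
interval), $n = 100\,000$ for marginal calibration checks (binomial
standard errors ≈ 0.16 % on the largest shares), and smaller cohorts
elsewhere. Optimizer defaults are `maxit = 500`, `reltol = 1e-10`
(tightened to `1e-14` where a $10^{-8}$ oracle agreement is asserted).
Tie-breaks are deterministic: a modal-frequency tie takes the first
category in declared order, with a warning. Percentages live as
proportions everywhere inside the package; formatting to percent
happens only in `print` methods and display layers.

## Limitations

The drift model is a two-bucket deterministic recursion: no
continuous-time hazards, no time-varying risk factors (a mutable factor
lets the population drift too, shrinking the attainable bias — the
model deliberately bounds the worst case), no sampling variability in
the trajectories. The generator inherits every simplification listed
above. Remedial analysis methods for attrition — multiple imputation,
random-effects or GEE longitudinal models, joint longitudinal-survival
models, stratification by time of death — are out of scope: this
package quantifies the bias, it does not correct it.
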