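---
title: "Methods: risk trajectories, BART multistate models, and standardization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk trajectories, BART multistate models, and standardization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices that a maintainer would
otherwise have to reverse-engineer from the code.

## 1. The estimand and the analysis chain

The package targets marginal (confounder-standardized) contrasts of
cumulative incidence between cardiovascular-risk *trajectory groups* in a
cohort observed at discrete 5-year waves. One row of the analysis chain:

FRS per wave → per-subject slope → trajectory class → discrete-time
multistate model with the class as exposure → standardized incidence per
class → RR(t), ARR, NNT.

Time is discrete at wave resolution throughout. All transition
intensities are per-interval conditional probabilities; nothing in the
package assumes proportional hazards or a continuous-time model. This
matches data collected at fixed 5-year visits, where finer timing of
events is simply not observed.

## 2. Office-based Framingham risk

`frs_risk()` evaluates `1 - S0^exp(LP - mean_lp)` with sex-specific
coefficients on log age, log BMI, log SBP (separate coefficients by
current antihypertensive treatment), smoking, and diabetes. The
coefficients, baseline survival, and mean linear predictor ship as a
versioned JSON file (`inst/extdata/frs_office_constants.json`) rather
than as code, so alternative coefficient sets can be swapped in; the
shipped values are the published office-based (BMI, non-laboratory)
general-CVD table and the test suite pins three reference profiles to an
independent arithmetic evaluation. The function was derived for ages
30–74; we deliberately do not cap ages (a 25-year follow-up of a
75-year-old entrant is routine here) but warn once per call, since
extrapolated risks should be read as indices rather than calibrated
10-year probabilities. When a subject's treatment status changes
mid-study, each wave is evaluated under that wave's status.

## 3. Slopes, pattern mixture, classification

Per subject, `fit_frs_slopes()` computes the OLS slope of risk against
years since the subject's first usable wave, using only pre-diagnosis
values and requiring at least `min_waves = 2` of them; subjects below the
minimum are carried as `unclassified`, never dropped. "In relation to age
and individual baseline risk" is operationalized as cross-subject linear
residualization of the raw slopes on baseline age and baseline FRS
(`adjust_slopes()`): it removes the mechanical tendency of risk to grow
faster at older ages and higher levels, without inventing a parametric
growth law. This is a genuine design choice; a latent-class growth
mixture model would be a plausible alternative and is deliberately out of
scope.

Dropout in aging cohorts is not ignorable — leavers are sicker.
`pattern_mixture_moments()` therefore stratifies subjects by dropout
pattern (last observed wave; intermittent gaps are folded into the last
wave with a usable value), estimates the slope mean and variance within
each pattern, and recombines them with pattern frequencies as weights;
the variance is weighted within- plus between-pattern dispersion (law of
total variance). With a single pattern this reduces exactly to the
ordinary mean/SD. Classification then applies the strict 1-SD rule to the
adjusted slopes: strictly above mean + SD is accelerated, strictly below
mean − SD is stable, boundaries inclusive to average.

Two properties shape what a user should expect. First, because each
subject's slope is estimated from their own observed window, the
pattern-mixture mean coincides with the frequency-weighted mean over all
classifiable subjects; its value over a complete-case mean materializes
exactly when dropout is linked to the slope itself, which the test suite
demonstrates on a constructed linear-trajectory scenario. Second, FRS is
convex in time (risk growth steepens with age and level), so slopes
measured over short windows understate long-run change for *every*
estimator; comparisons of slope estimators inside the package are
therefore made on linear constructions, and classification of real-shaped
trajectories should be read as relative, not absolute, rates of change.

## 4. The BART engine

`bart()` is a self-contained sum-of-trees sampler (Rcpp): trees get the
canonical regularization prior (split probability `0.95 (1+d)^-2`),
conjugate normal leaves scaled by `k = 2` (continuous: leaf SD
`0.5/(k sqrt(m))` after scaling the outcome to [-0.5, 0.5]; probit:
`3/(k sqrt(m))`), and, for continuous outcomes, a scaled inverse
chi-squared error variance with `nu = 3` placed so the naive outcome SD
sits at the `q = 0.90` quantile. Backfitting MCMC proposes grow, prune,
or change moves (0.25/0.25/0.50) accepted by Metropolis–Hastings on the
integrated leaf likelihood; binary outcomes use truncated-normal latent
augmentation with unit variance, sampled through stable tail quantiles.
Design simplifications, chosen once: no swap proposal (grow/prune/change
reach the same state space; the change move operates on nodes whose
children are both leaves), at most 100 quantile-based cutpoints per
continuous feature, a minimum leaf size of 5, and all randomness drawn
from R's RNG so `set.seed()` makes any fit exactly reproducible.
Posteriors serialize to JSON with doubles encoded as `%.17g` strings,
which makes reload-and-predict bit-identical — the cheap way to make
"same pipeline, same results" testable across sessions.

The sampler's mechanics are validated two ways that are worth knowing
about: in a likelihood-flat regime (`k` enormous) tree sizes reproduce
the structure prior's analytical leaf distribution, and on separable and
step-function targets the fit reaches the noise floor. One behavior is
intrinsic and documented rather than "fixed": on pure-noise features the
*pointwise* posterior-mean probability wobbles around the base rate
(SD ≈ 0.06–0.08 at n = 1000) even though the *averaged* (standardized)
probability is calibrated to within a few percent. Every quantity this
package reports downstream is an average over a pseudodata distribution,
which is why the standardization layer inherits calibration even though
single profiles are noisy.

## 5. Multistate decomposition and person-period expansion

The illness-death model (healthy → dementia, healthy → dead, dementia →
dead), its AD/VaD-split refinement, and the two-state decline model are
all decoupled into transition-specific binary models on person-period
tables (`person_period()`): interval `k` covers (wave k, wave k+1], a
subject contributes rows while occupying the origin state under
observation, dropout censors at the last observed wave, and dementia
onset is placed at the diagnosis wave (no backdating — onset between
waves is unobservable here). A subject first seen demented at wave k+1
enters the dementia→death risk set at interval k+1; same-wave dementia
and death cannot co-occur because states are recorded once per wave, and
the generator records dementia first with death possible from the next
interval. Covariates are frozen at baseline (the standardization target
is the baseline-confounder distribution); the interval index enters the
tree ensemble as an ordinary feature, so each transition's hazard is
freely time-varying and interacts freely with covariates —
nonproportionality costs nothing.

Competing exits from one origin are fitted as separate probit-BART
intensities. Within the forward recursion (`occupancy_recursion()`), a
draw whose summed exit probabilities exceed 1 is renormalized for that
interval only (counted; with realistic hazards it essentially never
fires), which keeps mass conservation exact: occupancy rows sum to 1 to
1e-9 by construction, and the test suite asserts it. The discrete-time
nonparametric benchmark (`cuminc_nonparametric()`) runs the *same*
recursion on count-based hazards (events over at-risk, the
Aalen–Johansen-type estimator), so model-vs-model-free comparisons differ
only in where the hazards come from.

## 6. Standardization

`standardize()` implements Bayesian g-computation: resample pseudodata
rows from the empirical joint baseline-confounder distribution
(preserving dependence; subgroup analyses condition the source rows
first), set every row's trajectory class to the target group, push each
row through the forward recursion under each retained posterior draw, and
average rows within draw. The posterior spread of the resulting curves
carries the uncertainty; `risk_ratio()` contrasts two curves draw by draw
on cumulative incidence (not hazards — the incidence scale is what the
reported contrasts are about) with equal-tailed 95% intervals, reporting
waves with zero denominator incidence as missing rather than infinite.
`arr_nnt()` takes the posterior-mean incidence difference at a reference
wave (default: final wave, whole-sample standardization) and
`NNT = nearest integer to 1/ARR`; the reference-wave choice is
configurable because the basis of the printed whole-sample figures is not
fully specified anywhere we could check. Defaults of 10,000 pseudodata
rows and 1,000 curve draws keep Monte-Carlo error negligible; the test
suite runs smaller (hundreds of rows, 100–500 draws) after verifying that
doubling the pseudodata moves posterior-mean RRs by well under 0.05.

## 7. Episodic-memory decline

The composite is the exact sum of five recall-task scores (0–76).
"Relative decline" is operationalized — the original study's exact rule
is in unavailable supplementary material, so ours is a declared stand-in:
residualize each composite against the mean of same-wave peers within ±5
years of age, and call the first wave at which the residual falls ≥ 1
pooled SD below the subject's own baseline residual the decline event;
otherwise censor at the last observation. Events are monotone in the
threshold by construction. Eligibility mirrors the age split of the
dementia analyses: entry age ≤ 65 for decline, ≥ 70 for dementia. Because
the rule is declared rather than reproduced, every test on this module is
property-based (direction, monotonicity, hand-computed toys), never a
numeric match to published decline counts.

## 8. The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a Betula-like cohort: six
5-year waves; entry ages on the 35–80 grid with the 70+ groups
down-weighted (0.6) to mimic early attrition of the oldest recruitment
groups; a 0.18/0.60/0.22 accelerated/average/stable mixture whose classes
share one baseline covariate distribution and differ only in slopes
(so baseline risk is similar across classes and the signal is genuinely
longitudinal); discrete-time transitions with dementia concentrated above
age 75 and only above 65 by hard rule; per-wave dropout with marginal
rates 1.5/6/30/39% at waves 3–6 whose nonignorability multiplier
(`exp(0.7)`) shifts dropout toward subjects with a latent dementia/death
path *without* changing the marginal rate; MAR item masking driven by
observed age and sex; and a memory composite (mean 35, SD 12) with a
−0.35/yr age slope and an equal extra decline in the accelerated class.
Event-rate parameters were calibrated once, by simulation, to the
older-stratum outcome proportions (≈ 32% AD, 16% VaD, ≈ 40–45% death
among 70+ entrants); whole-cohort dementia ends up somewhat above the
real study's because a 25-year follow-up carries younger entrants into
high-risk ages, a structural feature we chose not to suppress. Per-class
covariate slope magnitudes are not reported anywhere, so the defaults
(e.g., SBP +1.5 / +0.5 / −0.3 mmHg/yr) were chosen once as clinically
plausible rates that make the three groups distinguishable but
overlapping.

What passing tests on this generator do **not** show about real data:
measurement error here is Gaussian and independent across waves; dementia
ascertainment stops at dropout (a registry-based study would catch
diagnoses after the last visit); covariate trajectories are linear in
time within subject; and diagnostic adjudication, practice effects on
cognitive tests, and imaging are not modeled at all. Recovery results
should be read as "the estimator does what it claims under its stated
assumptions", not as external validation.

## 9. Problem sizes and numerical choices

The shipped tests run the full chain at cohort sizes of 800–2,000
subjects with 10–20 trees and 80–500 retained draws — sizes chosen so
that the whole suite exercises every claim at Monte-Carlo error well
inside each asserted tolerance. The three sizes that matter if you scale
up: person-period rows grow linearly in subjects × waves; a probit fit is
O(iterations × trees × rows); standardization is O(draws × pseudodata ×
waves × trees). Degenerate inputs are handled explicitly: constant
continuous outcomes return a degenerate posterior (with a message),
single-class binary outcomes and zero-event transitions raise named
errors, zero slope dispersion classifies everyone as average (with a
message), and configuration errors name the offending field. Ties at
classification boundaries go to the average class by the strict
inequality in the rule's definition.
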