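---
title: "Methods: simulating and analysing variable medication adherence in chronic epilepsy models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing variable medication adherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherogram)
```

## The paradigm

adherogram models a preclinical medication-in-food paradigm for chronic
epilepsy: rats with spontaneous recurring seizures receive their entire
daily chow ration (60 g/kg/day) as automated meals four times a day
(15 g/kg, q.i.d.), with antiseizure drug formulated into the pellets.
After a 4-week placebo baseline, a fully adherent group receives
medicated meals at every slot (10 mg/kg/day, i.e. 2.5 mg/kg per meal),
while a variably nonadherent group receives medicated meals for only
half of its meals, re-randomized within each calendar week. The
scientific questions the analysis layer addresses are (i) whether
partial adherence worsens seizure control relative to full adherence,
and (ii) whether particular short-term patterns of missed doses raise
or lower the odds of a breakthrough seizure.

Because the in-vivo data of such studies are not publicly deposited,
the package pairs every analysis with a synthetic-data generator that
reproduces the statistical structure the analyses assume. All
generator defaults *are* the study conditions: 10 fully adherent and
12 partially adherent animals, 4 + 4 week phases, q.i.d. meals,
weekly-exact 50% randomization, and a feeder failure probability of
12/4928 (the observed error rate of the automated feeder).

## Synthetic animals and seizures

Baseline seizure rates are drawn i.i.d. from a lognormal distribution,
`meanlog = log(5)`, `sdlog = 0.6` (median 5 convulsive seizures per
week, 95% of animals roughly between 1.5 and 16). Chronic
post-status-epilepticus models show order-of-magnitude inter-animal
variability and enroll animals at a floor of one stage-3+ seizure per
week; the default median sits comfortably above that floor so that
enrollment attrition stays small, while the spread preserves the
heterogeneity that motivates within-animal baseline normalization.
The lognormal family and these two constants are a modelling choice —
the field reports variability but no distribution.

Seizure streams are inhomogeneous Poisson processes simulated by
thinning at base hazard `baseline_rate/168` per hour. Racine scores
are categorical; the default puts uniform mass on convulsive stages
3–5 because enrollment and outcome definitions only distinguish
stage 3+ events, and no empirical score distribution is available.
Clusters are generated by letting each accepted event spawn, with
probability `cluster_propensity` (default 0.25), `min(1 +
Geometric(0.5), 3)` extra seizures placed uniformly within the same
6-h inter-meal interval — matching the operational definition of a
cluster as two or more seizures between mealtimes.

Three exposure-to-hazard effect models are provided:

* **null** — seizures independent of medication; the calibration
  condition for every association analysis.
* **conc_hazard** — hazard multiplied by
  `1 − max_reduction · C(t)/(C(t)+c50)`: a saturating, purely
  pharmacokinetic effect. In the saturating regime (`c50` far below
  the steady-state trough) the treatment-phase rate tends to
  `(1 − max_reduction)` times baseline, which is what makes parameter
  recovery testable: `max_reduction = 0.5` must return a median
  frequency change near −50%.
* **pattern_memory** — hazard multiplied by `1 − max_reduction`
  exactly when every meal in the trailing 24 h was medicated and
  delivered: a non-pharmacokinetic "recent full adherence" effect
  that reproduces, in simulation, the qualitative finding that full
  24-h adherence lowers seizure odds while single missed doses do
  nothing detectable.

## Pharmacokinetics

Plasma concentration is reconstructed by superposition of
one-compartment first-order absorption (Bateman) curves over the
medicated, delivered meals:

$$C(t) = \sum_{d} s\,D_d\,\frac{k_a}{k_a-k_e}\left(e^{-k_e(t-t_d)} -
e^{-k_a(t-t_d)}\right),\qquad k_e = \ln 2 / t_{1/2}.$$

Only the elimination half-life is empirically constrained
(`t½ = 1.67` h in rodents for the modelled drug). Absorption is
assumed fast oral, `ka = 3`/h; the analytic limits for `ka = ke` and
`ka = ∞` are implemented so no parameter combination divides by zero.
The dose-to-concentration scale is calibrated so that the fully
adherent default paradigm averages 425 ng/ml at steady state — the
reference effective plasma level in adult patients. The calibration
is purely presentational: every association analysis is invariant to
`scale`, and the one PK quantity checked quantitatively (the
full-to-half group ratio of weekly post-meal samples) equals the
inverse adherence fraction by linearity regardless of `scale`, `ka`
or `t½`. Weekly therapeutic drug monitoring is emulated as one sample
per treatment week, 1 h after the first scheduled meal of the week,
with values below the assay's 5 ng/ml limit of quantification
flagged.

A missed q.i.d. dose leaves a 6-h gap, about four half-lives, so
trough concentrations under partial adherence collapse almost to
zero between medicated meals. That is precisely why the
`pattern_memory` model is interesting: it encodes protection that
concentrations cannot explain.

## Outcome metrics

* **Enrollment**: animals need ≥ 1 stage-3+ seizure per week averaged
  over the baseline phase. The inclusive `≥` is the default because
  the criterion is phrased both inclusively and strictly in the
  literature this paradigm derives from; `strict = TRUE` switches to
  `>`.
* **Seizure burden** is the plain sum of Racine scores; it is
  computed from *raw* seizures. Cluster collapsing is applied only in
  the association analyses, where it prevents a single cluster from
  multiply counting one meal pattern.
* **Normalized change** is the percent change of the weekly seizure
  rate relative to the animal's own baseline. With equal-length
  phases this is identical whether computed from weekly rates or raw
  counts, so the ambiguity in how published medians were computed is
  moot here; we compute rates.
* **Responder summaries** count >25% and >50% reductions (strict
  inequalities, so exactly −50% is not a responder) and seizure
  freedom (−100%). The median's 95% CI uses the distribution-free
  binomial order-statistic interval, chosen because published tables
  do not name their CI method and the order-statistic interval makes
  no distributional assumption at these small n; its coverage is
  conservative (≥ 95%).

## Association analyses

**Meal-position table.** For every collapsed event, position *k*
looks up the *k*-th meal counting backwards, with position 1 the meal
opening the inter-meal interval that contains the event (the last
meal delivered before the seizure). Counts pool across animals; each
position gets an exact two-tailed binomial test against the scheduled
adherence fraction (0.5) and a Wilson score CI. Two bookkeeping rules
are our decisions where the source material is silent: positions that
would reach before the treatment phase are dropped from that
position's denominator (baseline meals are placebo by construction
and would mechanically drag early-study positions toward 0%), and an
undelivered meal counts as unmedicated — it delivered no drug.

**Pattern odds ratios.** The largest underdetermined design choice in
this analysis family is what denominates the odds ratio. We anchor a
window at *every* meal slot with a full day of preceding meals: the
window is the medication bit-pattern of the `meals_per_day` meals
ending at the anchor (oldest meal first), and the outcome is whether
the inter-meal interval opened by the anchor contains a collapsed
event. This uses all exposure time, makes every 2×2 table
well-defined, and under null simulation calibrates cleanly (all 16
CIs cover 1 at ≈ 95%). Consecutive windows overlap by
`meals_per_day − 1` meals; overlap means window outcomes are not
independent, which Wald CIs ignore — acceptable under calibration
checks, disclosed here. A non-overlapping stride and a case-only mode
(pattern frequencies among seizure-preceding windows versus their
overall frequencies) are available as options, since it cannot be
established which denominator published analyses used.

Zero cells take the Haldane–Anscombe 0.5 correction on all four
cells; CIs are Wald on the log odds ratio, `z = log(OR)/SE`, and the
p-value is the Pearson chi-square (no Yates correction by default, a
flag enables it). Grouped (0/25/50/75/100% adherence level) and
scenario tables (final-k doses missed, ≥2 consecutive missed, all
missed, full adherence) reuse the same window engine, so their counts
partition the same denominator.

**Statistical primitives.** All tests used anywhere in the pipeline —
exact two-tailed binomial (minimum-likelihood convention, with
doubled-one-tail as an option), Wilson CI, 2×2 odds ratio, exact and
approximate Mann–Whitney, Fisher exact, Spearman correlation, and a
permutation group-by-time interaction test (the in-package
alternative to repeated-measures ANOVA, which is out of scope) — are
implemented self-contained and verified in the test suite against
brute-force enumeration oracles on all instances with n ≤ 12, and
against the corresponding base-R tests as an independent
cross-check. The minimum-likelihood convention was chosen for the
two-tailed binomial because it is the common convention in prior
rodent-adherence analyses; at the pooled-event scale (~200 events per
position) its discrete size is ≈ 0.043 at nominal 0.05.

## Numerical and degenerate-input choices

* All times are decimal hours from study start (0-based); the meal at
  time *t* opens the half-open interval `[t, t + 6)`. Phases are
  labelled explicitly, never inferred.
* Seizures before an animal's first meal collapse into a flagged
  "pre-study" event that the association analyses exclude.
* `findInterval` handles interval assignment, so boundary seizures at
  exactly a mealtime belong to the interval that mealtime opens.
* The Bateman kernel switches to its analytic `ka → ke` limit within
  a relative tolerance of 1e-9, and to pure exponential decay for
  `ka = ∞`. Flip-flop kinetics (`ka < ke`) are rejected at
  construction.
* The exact Mann–Whitney null distribution comes from a subset-sum
  dynamic programme over pooled ranks (used when `min(n) ≤ 8` and no
  ties); tied or larger samples use the normal approximation with tie
  and continuity corrections.
* Steady-state periodicity of the PK profile is verified numerically
  to 1e-6 after more than ten half-lives.
* All randomness flows from one integer seed per study; identical
  configuration and seed reproduce byte-identical event logs.

## Problem sizes used in the test suite

Calibration tests run at sizes chosen so Monte-Carlo noise is
negligible relative to the asserted bands: the meal-position null
calibration pools ≥ 2,000 collapsed events from 250 simulated
partially adherent animals (per-position binomial SE ≈ 0.7
percentage points against a ±2.5-point band); odds-ratio CI coverage
averages 80 pattern CIs over five 50-animal null studies; parameter
recovery uses 50 animals per scenario. A full default study (22
animals, 8 weeks) simulates and analyses in a few seconds.

## What passing tests do and do not show

The generator reproduces the *designed* structure of the paradigm —
schedules, randomization blocks, feeder errors, heterogeneous
Poisson seizure streams with clusters, short-half-life PK — so green
calibration and recovery tests show the analysis code is correct and
well-calibrated *under that structure*. Real seizure diaries have
features the generator deliberately omits: circadian and multi-day
rhythms in seizure timing, rate nonstationarity (progression),
cluster dynamics richer than within-interval copies,
dose-history-dependent pharmacodynamics, and body-weight drift.
Conclusions about real data therefore inherit the usual caveats;
the package's claim is methodological, not biological.

## Known limitations

* Overlapping windows violate the independence assumed by Wald CIs;
  calibration is checked empirically instead of analytically.
* No animal-level random effects in the association step — events
  pool across animals, matching the published analysis style but
  ignoring within-animal correlation.
* One-compartment PK with assumed absorption; no brain:plasma
  partitioning, protein binding or metabolic induction.
* The repeated-measures ANOVA / mixed-model analyses of the source
  paradigm are represented only by the permutation interaction test.
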