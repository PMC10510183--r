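# adherogram

Simulation and analysis of **variable medication-adherence paradigms**
in preclinical chronic-epilepsy studies.

In medication-in-food paradigms, rats with chronic epilepsy receive
their daily chow as automated q.i.d. meals with antiseizure drug
formulated into the pellets (10 mg/kg/day at 60 g/kg/day feeding →
0.167 mg drug per g pellet, 2.5 mg/kg per meal). A fully adherent
group is medicated at every meal; a variably nonadherent group at a
random half of its meals, re-randomized weekly. Seizures are scored on
the Racine scale from continuous video-EEG. The analytical questions:
does partial adherence worsen seizure control, and do particular 24-h
patterns of missed doses change the odds of a breakthrough seizure?

adherogram provides, for users who design or analyse such paradigms:

* **Synthetic studies** (`gen_study()`): heterogeneous lognormal
  baseline seizure rates, weekly-blocked adherence randomization,
  feeder errors, inhomogeneous-Poisson seizure streams with clusters,
  and configurable exposure→hazard effect models (`null`,
  concentration-dependent, or 24-h "pattern memory").
* **PK reconstruction** (`concentration_profile()`): one-compartment
  Bateman superposition over delivered medicated meals
  (`t½ = 1.67 h`), with weekly therapeutic-drug-monitoring emulation
  (`tdm_sample()`).
* **Outcome metrics**: enrollment filtering (≥1 stage-3+
  seizure/week), seizure burden (sum of Racine scores),
  baseline-normalized percent change, responder summaries with
  order-statistic median CIs, Mann–Whitney and Fisher group
  comparisons.
* **Association analyses**: the meal-position table (percent
  medicated at each of the 10 meals preceding a seizure, exact
  binomial tests vs 50%) and meal-anchored 24-h adherence-pattern
  odds ratios — per pattern (2⁴ = 16 under q.i.d.), per grouped
  adherence level (0–100%), and per nonadherence scenario — with
  Haldane-corrected ORs, Wald CIs on the log-OR and chi-square
  p-values. Seizure clusters are collapsed to one event per
  inter-meal interval first (`collapse_clusters()`).
* **Self-contained statistics** (`binom_test_two_tailed()`,
  `fisher_exact_2x2()`, `mann_whitney_u()`, `spearman_rho()`,
  `odds_ratio_2x2()`, `permutation_interaction_test()`), each
  verified against brute-force enumeration oracles in the test suite.

## Worked example

Simulate the canonical paradigm (10 fully adherent + 12 variably
nonadherent animals, 4 + 4 weeks) with a protective "full 24-h
adherence" effect, and run every analysis:

```r
library(adherogram)
rep <- run_pipeline(list(
  n_full = 10, n_half = 12, seed = 42,
  effect = list(kind = "pattern_memory", max_reduction = 0.5)
), quiet = TRUE)

rep$meal_position
#> Medicated-meal distribution before seizures (expected 50%)
#>  position   n observed_pct         ci95     p
#>         1 215         48.8 [42.2, 55.5] 0.785
#>         2 214         44.9 [38.3, 51.6] 0.151
#>         3 213         47.9 [41.3, 54.6] 0.584
#>  ...
subset(rep$patterns, label %in% c("0000", "1111"))
#>  pattern windows w/seizure    OR           ci95       p
#>     0000      80        14 1.124 [0.619, 2.041] 0.70200
#>     1111      72         3 0.217 [0.068, 0.697] 0.00489
```

Read: no single meal position before a seizure deviates from the
scheduled 50% medicated (every binomial p is large), and the
completely missed day ("0000") shows no excess risk — but windows of
*full* 24-h adherence ("1111") have strongly reduced seizure odds
(OR 0.217, CI excluding 1), which is exactly the non-pharmacokinetic
protection this simulation injected. `rep$responders`, `rep$levels`
and `rep$scenarios` hold the responder-rate, grouped-adherence and
scenario tables; `write_report(rep, "report.json")` serializes the
bundle. A thin CLI over the same functions is installed at
`inst/cli/adherogram.R`.

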