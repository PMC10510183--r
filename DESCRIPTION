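Package: adherogram
Title: Simulation and Analysis of Variable Medication-Adherence Paradigms in
    Chronic Epilepsy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the relationship between missed antiseizure
    medication doses and breakthrough seizures in preclinical
    medication-in-food paradigms. Generates fully synthetic studies (animals
    with heterogeneous baseline seizure rates, randomized q.i.d. meal
    schedules with weekly-blocked partial adherence, point-process seizure
    streams, and therapeutic drug monitoring samples), reconstructs plasma
    drug exposure under arbitrary adherence schedules with a one-compartment
    first-order absorption model, computes seizure-burden and responder
    outcome metrics normalized to a within-animal baseline, and implements
    the meal-position binomial analysis and 24-hour adherence-pattern
    odds-ratio analysis linking adherence patterns to seizure incidence.
    Exact and approximate statistical primitives (two-tailed binomial,
    Fisher exact, Mann-Whitney, Spearman, 2x2 odds ratios, permutation
    interaction test) are implemented self-contained and verified against
    brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
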