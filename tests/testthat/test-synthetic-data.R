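test_that("cohort generation honours group sizes, heterogeneity and determinism", {
  an <- gen_animals(10, 12, seed = 1)
  expect_equal(nrow(an), 22)
  expect_equal(sum(an$group == "FULL"), 10)
  expect_equal(sum(an$group == "HALF"), 12)
  expect_false(anyDuplicated(an$animal_id) > 0)
  expect_true(all(an$baseline_rate > 0))
  expect_identical(an, gen_animals(10, 12, seed = 1))
  expect_equal(nrow(gen_animals(0, 0)), 0)
  # zero-variance limit pins every rate at the median
  an3 <- gen_animals(5, 5, rate_meanlog = log(3), rate_sdlog = 0, seed = 2)
  expect_equal(an3$baseline_rate, rep(3, 10))
  expect_error(gen_animals(-1, 5))
  expect_error(gen_animals(2.5, 5))
})

test_that("schedule layout: slot times, phases and per-group medication", {
  d <- study_design()
  full <- gen_schedule(one_animal("FULL"), d, seed = 5)
  expect_equal(nrow(full), 224)                       # 8 wk x 28 meals/wk
  expect_equal(full$time_h, (0:223) * 6)
  expect_equal(sum(full$phase == "BASELINE"), 112)
  expect_false(any(full$medicated[full$phase == "BASELINE"]))
  expect_true(all(full$medicated[full$phase == "TREATMENT"]))
  expect_equal(unique(full$dose_mg_per_kg[full$medicated]), 2.5)
  # HALF at adherence 1 reproduces the FULL medication pattern
  d1 <- study_design(adherence_fraction_half = 1)
  half1 <- gen_schedule(one_animal("HALF"), d1, seed = 5)
  expect_equal(half1$medicated, full$medicated)
})

test_that("weekly-exact randomization medicates exactly half of each week's meals", {
  d <- study_design()
  for (seed in c(2, 17, 91)) {
    m <- gen_schedule(one_animal("HALF"), d, seed = seed)
    trt <- m[m$phase == "TREATMENT", ]
    week <- (trt$time_h - treatment_start(d)) %/% 168
    counts <- tapply(trt$medicated, week, sum)
    expect_equal(as.vector(counts), rep(14, 4))
  }
  # bernoulli mode has no fixed weekly count but respects the fraction
  db <- study_design(randomization_block = "bernoulli")
  m <- gen_schedule(one_animal("HALF"), db, seed = 2)
  frac <- mean(m$medicated[m$phase == "TREATMENT"])
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
})

test_that("feeder errors are rare, seed-stable and zero out delivered doses", {
  d <- study_design(feeder_error_rate = 0.2)
  m <- gen_schedule(one_animal("FULL"), d, seed = 8)
  expect_gt(sum(!m$delivered), 0)
  expect_identical(m, gen_schedule(one_animal("FULL"), d, seed = 8))
  d0 <- study_design(feeder_error_rate = 0)
  expect_true(all(gen_schedule(one_animal("FULL"), d0, seed = 8)$delivered))
})

test_that("null-effect seizure stream is Poisson with the nominal mean", {
  a <- one_animal(rate = 7, cluster = 0)
  m <- gen_schedule(a, study_design(), seed = 1)
  set.seed(2)
  totals <- replicate(300, nrow(gen_seizures(a, m)))
  # Poisson mean = 7/week x 8 weeks = 56; MC tolerance +/- 2
  expect_equal(mean(totals), 56, tolerance = 2 / 56)
  expect_equal(var(totals), 56, tolerance = 0.25)
})

test_that("seizure events stay in the study window with valid Racine scores", {
  a <- one_animal(rate = 12, cluster = 0.5)
  m <- gen_schedule(a, study_design(), seed = 3)
  s <- gen_seizures(a, m, seed = 4)
  expect_true(all(s$time_h >= 0 & s$time_h <= study_span(study_design())))
  expect_true(all(s$racine %in% 1:5))
  expect_true(all(s$racine %in% 3:5))     # default mass on stages 3-5
  expect_false(is.unsorted(s$time_h))
  s2 <- gen_seizures(a, m, racine_probs = c(1, 0, 0, 0, 0), seed = 4)
  expect_true(all(s2$racine == 1))
})

test_that("saturating concentration effect suppresses treatment-phase seizures", {
  a <- one_animal(group = "FULL", rate = 20, cluster = 0)
  d <- study_design(feeder_error_rate = 0)
  m <- gen_schedule(a, d, seed = 6)
  eff <- effect_model("conc_hazard", c50 = 1e-6, max_reduction = 1 - 1e-9)
  s <- gen_seizures(a, m, pk_params(), eff, seed = 7)
  trt <- s$time_h >= treatment_start(d) + 1   # allow absorption onset
  expect_equal(sum(trt), 0)
  expect_gt(sum(!trt), 0)                     # baseline untouched
})

test_that("pattern-memory multiplier engages exactly on full trailing adherence", {
  meals <- toy_meals(9, med = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
                                TRUE, TRUE))
  eff <- effect_model("pattern_memory", max_reduction = 0.4,
                      memory_window_h = 24)
  mult <- adherogram:::hazard_multiplier(
    c(19, 25, 42.5, 47.9), meals, pk_params(), eff)
  # t=19: meals at 0,6,12,18 all medicated -> reduced
  # t=25: meals at 6,12,18,24 include the missed meal 5 (t=24) -> full
  # t=42.5: meals at 24,30,36,42 include miss -> full hazard
  # t=47.9: meals at 24..42 still include miss at 24 -> full hazard
  expect_equal(mult, c(0.6, 1, 1, 1))
  # after the miss clears the 24-h window the reduction re-engages
  expect_equal(adherogram:::hazard_multiplier(48.5, meals, pk_params(), eff), 0.6)
})

test_that("non-null effects require a meal schedule", {
  a <- one_animal()
  empty <- toy_meals(0)
  expect_error(gen_seizures(a, empty, effect = effect_model("conc_hazard")),
               "meal schedule")
})

test_that("full study composition is reproducible and correctly sized", {
  st <- gen_study(10, 12, seed = 99)
  expect_equal(nrow(st$meals), 22 * 224)               # 4,928 meals
  expect_equal(nrow(st$plasma), 22 * 4)
  st2 <- gen_study(10, 12, seed = 99)
  expect_identical(st$meals, st2$meals)
  expect_identical(st$seizures, st2$seizures)
  st3 <- gen_study(10, 12, seed = 100)
  expect_false(identical(st$meals$medicated, st3$meals$medicated))
  # design counts are seed-invariant
  expect_equal(nrow(st3$meals), nrow(st$meals))
  expect_true(all(st$seizures$animal_id %in% st$animals$animal_id))
  expect_true(all(st$meals$animal_id %in% st$animals$animal_id))
})
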