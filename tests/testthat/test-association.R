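# Small deterministic schedule for association tests: one animal, 12
# treatment meals with a known medication pattern.
assoc_meals <- function(med) toy_meals(length(med), med = med)

test_that("pattern enumeration covers all 2^k patterns in canonical order", {
  p4 <- enumerate_patterns(4)
  expect_equal(nrow(p4), 16)
  expect_equal(p4$pattern[1], "0000")
  expect_equal(p4$pattern[16], "1111")
  expect_equal(p4$pattern[2], "0001")       # newest meal = least significant
  expect_equal(p4$n_medicated, vapply(strsplit(p4$pattern, ""),
                                      function(b) sum(b == "1"), numeric(1)))
  expect_equal(nrow(enumerate_patterns(1)), 2)
  expect_equal(nrow(enumerate_patterns(3)), 8)
  expect_error(enumerate_patterns(17))
  expect_error(enumerate_patterns(0))
})

test_that("meal positions are looked up backwards from the event interval", {
  # meals: med pattern known; seizure at t=27 sits in interval of meal 5
  med <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  m <- assoc_meals(med)
  cc <- collapse_clusters(toy_seizures(27), m)
  expect_equal(cc$interval_index, 5)
  mp <- meal_position_table(cc, m, max_position = 6)
  # position 1 = meal 5 (unmedicated), position 2 = meal 4 (medicated) ...
  # position 6 would reach before the schedule and has no events
  expect_equal(mp$n_events, c(1, 1, 1, 1, 1, 0))
  expect_equal(mp$n_medicated, c(0, 1, 1, 0, 1, 0))
  expect_true(is.na(mp$pct_medicated[6]))
  # an event too early for deep positions drops out of those denominators
  cc2 <- collapse_clusters(toy_seizures(13), m)   # interval 3
  mp2 <- meal_position_table(cc2, m, max_position = 6)
  expect_equal(mp2$n_events, c(1, 1, 1, 0, 0, 0))
  # undelivered medicated meal counts as unmedicated
  m3 <- m; m3$delivered[5] <- FALSE; m3$medicated[5] <- TRUE
  mp3 <- meal_position_table(cc, m3, max_position = 1)
  expect_equal(mp3$n_medicated, 0L)
})

test_that("baseline meals are excluded from position denominators", {
  m <- assoc_meals(rep(TRUE, 8))
  m$phase[1:4] <- "BASELINE"
  m$medicated[1:4] <- FALSE
  cc <- collapse_clusters(toy_seizures(27), m)    # interval 5
  mp <- meal_position_table(cc, m, max_position = 4)
  expect_equal(mp$n_events, c(1, 0, 0, 0))        # meals 4,3,2 are baseline
  mp_all <- meal_position_table(cc, m, max_position = 4,
                                restrict_phase = NULL)
  expect_equal(mp_all$n_events, rep(1, 4))
})

test_that("fully adherent misuse yields 100% medicated at every position", {
  m <- assoc_meals(rep(TRUE, 12))
  cc <- collapse_clusters(toy_seizures(c(31, 55, 67)), m)
  mp <- meal_position_table(cc, m, max_position = 4)
  expect_true(all(mp$pct_medicated == 100))
  expect_true(all(mp$p_two_tailed < 0.26))   # 3 events each: p = 2*(1/8)
})

test_that("windows partition by pattern, level and scenario complements", {
  st <- gen_study(0, 6, seed = 31)
  cc <- collapse_clusters(st$seizures, st$meals)
  trt <- cc[cc$time_h >= treatment_start(st$design), ]
  w <- adherence_windows(trt, st$meals)
  pt <- pattern_or_table(trt, st$meals, windows = w)
  expect_equal(sum(pt$a + pt$b), nrow(w))
  expect_equal(sum(pt$a), sum(w$seizure))
  lv <- adherence_level_table(trt, st$meals, windows = w)
  expect_equal(nrow(lv), 5)
  expect_equal(sum(lv$a + lv$b), nrow(w))
  sc <- scenario_table(trt, st$meals, windows = w)
  expect_true(all(sc$a + sc$b + sc$c + sc$d == nrow(w)))
  # every window pattern is one of the 16
  expect_true(all(w$pattern_id %in% 0:15))
})

test_that("window construction anchors patterns and outcomes correctly", {
  med <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  m <- assoc_meals(med)
  cc <- collapse_clusters(toy_seizures(20), m)    # interval 4: [18, 24)
  w <- adherence_windows(cc, m)
  expect_equal(nrow(w), 5)                        # anchors at meals 4..8
  # anchor 4: bits of meals 1-4 = 1101 -> id 13; seizure in [18, 24) -> TRUE
  expect_equal(w$pattern_id[w$anchor == 4], 13)
  expect_true(w$seizure[w$anchor == 4])
  expect_false(any(w$seizure[w$anchor != 4]))
  # anchor 8: meals 5-8 = 0011 -> id 3
  expect_equal(w$pattern_id[w$anchor == 8], 3)
  # non-overlapping stride reduces the window count
  w4 <- adherence_windows(cc, m, stride = 4)
  expect_equal(nrow(w4), 2)
  # trivially balanced table gives OR 1 with CI spanning 1
  o <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(unname(o$estimate), 1)
})

test_that("scenario predicates match the advertised pattern subsets", {
  sc <- default_scenarios()
  pats <- enumerate_patterns(4)
  bits <- lapply(strsplit(pats$pattern, ""), function(b) b == "1")
  # final 3 missed: patterns x000 -> exactly 2 of 16
  expect_equal(sum(vapply(bits, sc[["final 3 missed"]], logical(1))), 2)
  # >=2 consecutive missed on pattern 1001 (oldest->newest) is TRUE
  expect_true(sc[[">=2 consecutive missed"]](c(TRUE, FALSE, FALSE, TRUE)))
  expect_false(sc[[">=2 consecutive missed"]](c(FALSE, TRUE, FALSE, TRUE)))
  expect_equal(sum(vapply(bits, sc[["all missed"]], logical(1))), 1)
  expect_equal(sum(vapply(bits, sc[["full adherence"]], logical(1))), 1)
  expect_equal(sum(vapply(bits, sc[["final dose missed"]], logical(1))), 8)
})

test_that("case-only mode reports pattern enrichment among seizure windows", {
  st <- gen_study(0, 8, seed = 77)
  cc <- collapse_clusters(st$seizures, st$meals)
  trt <- cc[cc$time_h >= treatment_start(st$design), ]
  ct <- pattern_or_table(trt, st$meals, mode = "case_only")
  expect_equal(nrow(ct), 16)
  expect_equal(sum(ct$a), attr(ct, "n_seizure_windows") * 1L)
  expect_true(all(ct$p >= 0 & ct$p <= 1, na.rm = TRUE))
})
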