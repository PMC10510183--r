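#' Generate a meal/medication schedule for one animal
#'
#' Lays out one meal per slot at `0, inter_meal_h, 2*inter_meal_h, ...`
#' hours from study start. Baseline-phase meals are always placebo. In the
#' treatment phase, `"FULL"` animals receive medicated meals at every
#' slot; `"HALF"` animals receive medicated meals according to the
#' design's randomization scheme — under `"weekly_exact"` exactly
#' `round(fraction * meals_per_week)` meals of every calendar week are
#' medicated, at uniformly random positions within the week. Each meal is
#' independently undelivered with probability `feeder_error_rate`
#' (feeder malfunction); an undelivered meal contributes no dose.
#'
#' @param animal A single-row data frame as produced by [gen_animals()]
#'   (only `animal_id` and `group` are used).
#' @param design A [study_design()].
#' @param seed Optional integer; if given, the RNG is seeded locally.
#' @return A data frame of meal events: `animal_id`, `time_h`, `phase`
#'   (`"BASELINE"`/`"TREATMENT"`), `medicated`, `delivered`,
#'   `dose_mg_per_kg` (per-meal dose if medicated, else 0).
#' @examples
#' a <- gen_animals(0, 1, seed = 1)
#' m <- gen_schedule(a, study_design(), seed = 2)
#' table(m$phase, m$medicated)
#' @export
gen_schedule <- function(animal, design = study_design(), seed = NULL) {
  stopifnot(inherits(design, "study_design"), nrow(animal) == 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_meals(design)
  time_h <- (seq_len(n) - 1) * design$inter_meal_h
  phase <- ifelse(time_h < treatment_start(design), "BASELINE", "TREATMENT")
  medicated <- rep(FALSE, n)
  trt <- which(phase == "TREATMENT")
  frac <- if (animal$group == "FULL") 1 else design$adherence_fraction_half
  if (animal$group == "FULL" || frac >= 1) {
    medicated[trt] <- TRUE
  } else if (frac > 0) {
    if (design$randomization_block == "weekly_exact") {
      meals_per_week <- design$meals_per_day * 7L
      k <- round(frac * meals_per_week)
      week <- (trt - trt[1]) %/% meals_per_week
      for (w in unique(week)) {
        slots <- trt[week == w]
        medicated[slots[sample.int(length(slots), min(k, length(slots)))]] <- TRUE
      }
    } else {
      medicated[trt] <- stats::runif(length(trt)) < frac
    }
  }
  delivered <- stats::runif(n) >= design$feeder_error_rate
  per_meal <- design$target_dose_mg_per_kg_day / design$meals_per_day
  data.frame(
    animal_id = animal$animal_id, time_h = time_h, phase = phase,
    medicated = medicated, delivered = delivered,
    dose_mg_per_kg = ifelse(medicated, per_meal, 0),
    stringsAsFactors = FALSE
  )
}
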