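#' Drug content of medicated chow
#'
#' Converts a target daily dose into the drug concentration that must be
#' formulated into the chow, given the daily feeding rate. For a
#' 10 mg/kg/day dose on a 60 g/kg/day feeding regimen this is
#' 0.167 mg drug per g pellet.
#'
#' @param dose_mg_per_kg_day Target daily dose, mg/kg/day.
#' @param feed_g_per_kg_day Daily chow ration, g/kg/day.
#' @return mg drug per g chow.
#' @examples
#' pellet_drug_content(10, 60)   # 0.1667
#' @export
pellet_drug_content <- function(dose_mg_per_kg_day, feed_g_per_kg_day) {
  if (any(dose_mg_per_kg_day <= 0) || any(feed_g_per_kg_day <= 0))
    stop("dose and feed rates must be positive")
  dose_mg_per_kg_day / feed_g_per_kg_day
}

#' Per-meal dose under divided daily dosing
#'
#' @param dose_mg_per_kg_day Daily dose, mg/kg/day.
#' @param meals_per_day Number of equally sized meals per day.
#' @return mg/kg delivered at each meal.
#' @examples
#' per_meal_dose(10, 4)   # 2.5 mg/kg q.i.d.
#' @export
per_meal_dose <- function(dose_mg_per_kg_day, meals_per_day) {
  if (any(meals_per_day < 1)) stop("meals_per_day must be >= 1")
  dose_mg_per_kg_day / meals_per_day
}

#' Plasma concentration profile under an adherence schedule
#'
#' Reconstructs `C(t)` by superposition of one-compartment first-order
#' absorption (Bateman) curves, one per medicated *and delivered* meal:
#' \deqn{C(t) = \sum_d s\,D_d \frac{k_a}{k_a-k_e}
#'   \left(e^{-k_e (t-t_d)} - e^{-k_a (t-t_d)}\right), \quad t \ge t_d,}
#' with `ke = ln 2 / half_life_h`. The analytic limits are used when
#' `ka = ke` (`s D ke (t-t_d) e^{-ke(t-t_d)}`) and when `ka = Inf`
#' (instantaneous absorption, `s D e^{-ke(t-t_d)}`). The profile is linear
#' in dose and exactly additive over dose sets.
#'
#' @param meals Meal-event data frame (see [gen_schedule()]); only rows
#'   with `medicated & delivered & dose > 0` contribute.
#' @param pk A [pk_params()].
#' @param times Numeric vector of times (hours) at which to evaluate.
#' @return Numeric vector of concentrations (ng/ml), same length as
#'   `times`.
#' @export
concentration_profile <- function(meals, pk = pk_params(), times) {
  stopifnot(inherits(pk, "pk_params"), is.numeric(times))
  act <- meals[meals$medicated & meals$delivered & meals$dose_mg_per_kg > 0, ,
               drop = FALSE]
  conc <- numeric(length(times))
  if (nrow(act) == 0) return(conc)
  if (is.unsorted(act$time_h)) act <- act[order(act$time_h), ]
  ke <- pk$ke_per_h
  ka <- pk$ka_per_h
  s <- pk$scale
  # dt[i, j] = times[i] - dose_time[j], negative entries contribute 0
  dt <- outer(times, act$time_h, "-")
  pos <- dt >= 0
  dt[!pos] <- 0
  if (!is.finite(ka)) {
    kern <- exp(-ke * dt)
  } else if (abs(ka - ke) < 1e-9 * ke) {
    kern <- ke * dt * exp(-ke * dt)
  } else {
    kern <- (ka / (ka - ke)) * (exp(-ke * dt) - exp(-ka * dt))
  }
  kern[!pos] <- 0
  as.numeric(kern %*% (s * act$dose_mg_per_kg))
}

#' Weekly therapeutic drug monitoring samples
#'
#' Emulates the weekly plasma draws of the paradigm: one sample per
#' treatment week per animal, taken `offset_h` hours (default 1) after the
#' first scheduled meal of the week. Concentrations come from
#' [concentration_profile()]; values below the assay's lower limit of
#' quantification are flagged.
#'
#' @param meals Meal-event data frame for one animal.
#' @param pk A [pk_params()].
#' @param design The [study_design()] that produced `meals`.
#' @param offset_h Sampling delay after the scheduled meal, hours.
#' @return Data frame: `animal_id`, `week` (treatment week, 1-based),
#'   `time_h`, `conc_ng_ml`, `below_lloq`.
#' @export
tdm_sample <- function(meals, pk = pk_params(), design = study_design(),
                       offset_h = 1) {
  stopifnot(nrow(meals) > 0)
  weeks <- seq_len(design$treatment_weeks)
  t_sample <- treatment_start(design) + (weeks - 1) * 168 + offset_h
  if (any(t_sample > study_span(design)))
    stop("sampling times fall outside the study span")
  conc <- concentration_profile(meals, pk, t_sample)
  data.frame(
    animal_id = meals$animal_id[1], week = weeks, time_h = t_sample,
    conc_ng_ml = conc, below_lloq = conc < pk$lloq_ng_ml,
    stringsAsFactors = FALSE
  )
}
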