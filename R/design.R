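#' Study design for a medication-in-food adherence paradigm
#'
#' Bundles the paradigm constants: phase lengths, meal schedule, feeding
#' rate, daily drug dose and the adherence randomization scheme for the
#' partially adherent group. Defaults reproduce the canonical design: a
#' 4-week placebo baseline followed by a 4-week treatment phase, four meals
#' per day at 6-h intervals (15 g/kg chow per meal, 60 g/kg/day), a target
#' dose of 10 mg/kg/day, and 50% adherence randomized in weekly blocks with
#' an exact half of each week's meals medicated.
#'
#' @param baseline_weeks Integer, length of the placebo baseline phase.
#' @param treatment_weeks Integer, length of the treatment phase.
#' @param meals_per_day Integer, meals per 24 h (q.i.d. = 4).
#' @param feed_g_per_kg_day Chow delivered per day, g/kg body weight.
#' @param target_dose_mg_per_kg_day Daily drug dose for a fully adherent
#'   animal, mg/kg/day.
#' @param adherence_fraction_half Fraction of meals medicated in the
#'   partially adherent (HALF) group.
#' @param randomization_block `"weekly_exact"` medicates exactly
#'   `round(fraction * meals per week)` meals in each treatment week at
#'   uniformly random positions (the delivered count is adjusted weekly);
#'   `"bernoulli"` medicates each meal independently.
#' @param feeder_error_rate Probability that a scheduled meal fails to be
#'   delivered. The default reflects 12 failures in 4,928 meals.
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$inter_meal_h            # 6
#' n_meals(d)                # 224 scheduled meals per animal
#' @export
study_design <- function(baseline_weeks = 4, treatment_weeks = 4,
                         meals_per_day = 4, feed_g_per_kg_day = 60,
                         target_dose_mg_per_kg_day = 10,
                         adherence_fraction_half = 0.5,
                         randomization_block = c("weekly_exact", "bernoulli"),
                         feeder_error_rate = 12 / 4928) {
  randomization_block <- match.arg(randomization_block)
  stopifnot(baseline_weeks >= 1, treatment_weeks >= 1, meals_per_day >= 1,
            feed_g_per_kg_day > 0, target_dose_mg_per_kg_day > 0,
            adherence_fraction_half >= 0, adherence_fraction_half <= 1,
            feeder_error_rate >= 0, feeder_error_rate < 1)
  if (24 %% meals_per_day != 0)
    stop("meals_per_day must divide 24 so that meals are equally spaced")
  structure(list(
    baseline_weeks = as.integer(baseline_weeks),
    treatment_weeks = as.integer(treatment_weeks),
    meals_per_day = as.integer(meals_per_day),
    inter_meal_h = 24 / meals_per_day,
    feed_g_per_kg_day = feed_g_per_kg_day,
    target_dose_mg_per_kg_day = target_dose_mg_per_kg_day,
    adherence_fraction_half = adherence_fraction_half,
    randomization_block = randomization_block,
    feeder_error_rate = feeder_error_rate
  ), class = "study_design")
}

#' @rdname study_design
#' @param design A `study_design`.
#' @export
n_meals <- function(design) {
  stopifnot(inherits(design, "study_design"))
  (design$baseline_weeks + design$treatment_weeks) * 7L * design$meals_per_day
}

#' Start of the treatment phase, hours from study start
#' @param design A `study_design`.
#' @return Time in hours at which the treatment phase begins.
#' @export
treatment_start <- function(design) design$baseline_weeks * 168

#' Total study span in hours
#' @param design A `study_design`.
#' @export
study_span <- function(design)
  (design$baseline_weeks + design$treatment_weeks) * 168

#' @export
print.study_design <- function(x, ...) {
  cat("Adherence study design\n")
  cat(sprintf("  phases: %d wk baseline + %d wk treatment\n",
              x$baseline_weeks, x$treatment_weeks))
  cat(sprintf("  meals: %d/day every %g h (%g g/kg/day chow)\n",
              x$meals_per_day, x$inter_meal_h, x$feed_g_per_kg_day))
  cat(sprintf("  dose: %g mg/kg/day (%g mg/kg per meal)\n",
              x$target_dose_mg_per_kg_day,
              x$target_dose_mg_per_kg_day / x$meals_per_day))
  cat(sprintf("  HALF-group adherence: %g (%s), feeder error rate %.4g\n",
              x$adherence_fraction_half, x$randomization_block,
              x$feeder_error_rate))
  invisible(x)
}

#' One-compartment pharmacokinetic parameters
#'
#' First-order absorption, first-order elimination. Only the elimination
#' half-life is constrained by rodent data (about 1.67 h for the modelled
#' drug); absorption is assumed fast oral (`ka = 3` per hour). The `scale`
#' parameter maps a 1 mg/kg dose to concentration units; its default is
#' calibrated so that the fully adherent default paradigm (2.5 mg/kg every
#' 6 h) has an average steady-state plasma level of about 425 ng/ml, the
#' reference effective level in adult patients. All association analyses
#' are invariant to `scale`.
#'
#' @param half_life_h Elimination half-life, hours.
#' @param ka_per_h First-order absorption rate constant, per hour. May be
#'   `Inf` for bolus-style instantaneous absorption.
#' @param scale Concentration (ng/ml) per unit dose (mg/kg) per unit of the
#'   disposition kernel; default calibrated as described above.
#' @param lloq_ng_ml Lower limit of quantification of the plasma assay.
#' @return An object of class `pk_params`.
#' @examples
#' pk <- pk_params()
#' log(2) / pk$half_life_h   # elimination rate constant, per hour
#' @export
pk_params <- function(half_life_h = 1.67, ka_per_h = 3.0, scale = NULL,
                      lloq_ng_ml = 5) {
  stopifnot(half_life_h > 0, ka_per_h > 0, lloq_ng_ml >= 0)
  ke <- log(2) / half_life_h
  if (is.finite(ka_per_h) && ka_per_h < ke)
    stop("ka_per_h < elimination rate: flip-flop kinetics not supported; ",
         "swap the constants or raise ka_per_h")
  if (is.null(scale)) {
    # average steady-state level for D mg/kg every tau h is scale*D/(ke*tau);
    # solve for scale at the default paradigm (2.5 mg/kg q6h) hitting 425
    scale <- 425 * ke * 6 / 2.5
  }
  stopifnot(scale > 0)
  structure(list(half_life_h = half_life_h, ke_per_h = ke,
                 ka_per_h = ka_per_h, scale = scale,
                 lloq_ng_ml = lloq_ng_ml),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "One-compartment PK: t1/2 = %g h (ke = %.3f/h), ka = %g/h, scale = %.1f, LLOQ = %g ng/ml\n",
    x$half_life_h, x$ke_per_h, x$ka_per_h, x$scale, x$lloq_ng_ml))
  invisible(x)
}

#' Exposure-to-hazard effect models for the seizure simulator
#'
#' Defines how medication modulates the seizure hazard in synthetic
#' studies.
#'
#' * `"null"`: the hazard is independent of medication. Used for
#'   calibration of the association analyses.
#' * `"conc_hazard"`: the hazard is multiplied by
#'   `1 - max_reduction * C(t) / (C(t) + c50)` where `C(t)` is the
#'   reconstructed plasma concentration — a saturating, purely
#'   pharmacokinetic effect.
#' * `"pattern_memory"`: the hazard is multiplied by `1 - max_reduction`
#'   whenever every meal in the trailing `memory_window_h` hours was
#'   medicated and delivered — a non-pharmacokinetic "full recent
#'   adherence" effect.
#'
#' @param kind Effect kind, see above.
#' @param c50 Concentration of half-maximal effect (same units as the PK
#'   profile), for `"conc_hazard"`.
#' @param max_reduction Maximal fractional hazard reduction, in [0, 1).
#' @param memory_window_h Width of the trailing adherence window in hours,
#'   for `"pattern_memory"`.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(kind = c("null", "conc_hazard", "pattern_memory"),
                         c50 = 50, max_reduction = 0.5,
                         memory_window_h = 24) {
  kind <- match.arg(kind)
  stopifnot(max_reduction >= 0, max_reduction < 1, c50 > 0,
            memory_window_h > 0)
  structure(list(kind = kind, c50 = c50, max_reduction = max_reduction,
                 memory_window_h = memory_window_h),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat("Effect model:", x$kind)
  if (x$kind == "conc_hazard")
    cat(sprintf(" (max_reduction = %g, c50 = %g)", x$max_reduction, x$c50))
  if (x$kind == "pattern_memory")
    cat(sprintf(" (max_reduction = %g, window = %g h)",
                x$max_reduction, x$memory_window_h))
  cat("\n")
  invisible(x)
}
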