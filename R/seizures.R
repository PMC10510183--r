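#' Simulate a scored seizure stream for one animal
#'
#' Seizure times follow an inhomogeneous Poisson process simulated by
#' thinning. The base hazard is `baseline_rate / 168` per hour (constant);
#' the [effect_model()] multiplies it by
#' * 1 under `"null"`,
#' * `1 - max_reduction * C(t)/(C(t) + c50)` under `"conc_hazard"`, and
#' * `1 - max_reduction` under `"pattern_memory"` whenever the full set of
#'   meals scheduled in the trailing `memory_window_h` hours was medicated
#'   and delivered.
#'
#' Each accepted event receives a Racine score drawn from `racine_probs`.
#' With probability `cluster_propensity` an event spawns a cluster:
#' `min(1 + Geometric(0.5), 3)` extra seizures placed uniformly within the
#' same inter-meal interval (clusters never recurse).
#'
#' @param animal Single-row animal data frame ([gen_animals()]).
#' @param meals Meal-event data frame for this animal, sorted by time.
#' @param pk A [pk_params()] (used by `"conc_hazard"` only).
#' @param effect An [effect_model()].
#' @param racine_probs Probabilities of Racine scores 1..5; default puts
#'   uniform mass on convulsive stages 3-5.
#' @param span_h Study span in hours; defaults to the end of the last
#'   inter-meal interval.
#' @param seed Optional integer; if given, the RNG is seeded locally.
#' @return Data frame of seizure events: `animal_id`, `time_h`, `racine`,
#'   sorted by time.
#' @export
gen_seizures <- function(animal, meals, pk = pk_params(),
                         effect = effect_model("null"),
                         racine_probs = c(0, 0, 1, 1, 1) / 3,
                         span_h = NULL, seed = NULL) {
  stopifnot(inherits(effect, "effect_model"), nrow(animal) == 1,
            length(racine_probs) == 5, all(racine_probs >= 0))
  if (nrow(meals) == 0) {
    if (effect$kind != "null")
      stop("non-null effect models require a meal schedule")
    meal_times <- numeric()
    gap <- 6
  } else {
    meal_times <- meals$time_h
    if (is.unsorted(meal_times)) stop("meals must be sorted by time")
    gap <- if (length(meal_times) > 1) min(diff(meal_times)) else 6
  }
  if (is.null(span_h))
    span_h <- if (length(meal_times)) max(meal_times) + gap else 8 * 168
  if (!is.null(seed)) set.seed(seed)

  lambda0 <- animal$baseline_rate / 168   # per hour; effects only reduce
  n_cand <- stats::rpois(1, lambda0 * span_h)
  if (n_cand == 0)
    return(data.frame(animal_id = character(), time_h = numeric(),
                      racine = integer(), stringsAsFactors = FALSE))
  t_cand <- sort(stats::runif(n_cand, 0, span_h))
  mult <- hazard_multiplier(t_cand, meals, pk, effect)
  keep <- stats::runif(n_cand) <= mult
  t_acc <- t_cand[keep]

  # seizure clusters: extras confined to the event's inter-meal interval
  extra_t <- numeric()
  if (length(t_acc) && animal$cluster_propensity > 0 && length(meal_times)) {
    spawns <- stats::runif(length(t_acc)) < animal$cluster_propensity
    for (t0 in t_acc[spawns]) {
      i <- findInterval(t0, meal_times)
      lo <- if (i >= 1) meal_times[i] else 0
      hi <- if (i < length(meal_times)) meal_times[i + 1] else span_h
      n_extra <- min(1 + stats::rgeom(1, 0.5), 3)
      extra_t <- c(extra_t, stats::runif(n_extra, lo, hi))
    }
  }
  all_t <- sort(c(t_acc, extra_t))
  data.frame(
    animal_id = rep(animal$animal_id, length(all_t)),
    time_h = all_t,
    racine = sample.int(5, length(all_t), replace = TRUE,
                        prob = racine_probs),
    stringsAsFactors = FALSE
  )
}

# Hazard multiplier in [0, 1] at each time under an effect model.
hazard_multiplier <- function(times, meals, pk, effect) {
  if (effect$kind == "null" || length(times) == 0)
    return(rep(1, length(times)))
  if (effect$kind == "conc_hazard") {
    conc <- concentration_profile(meals, pk, times)
    return(1 - effect$max_reduction * conc / (conc + effect$c50))
  }
  # pattern_memory: full trailing window medicated & delivered
  ok <- meals$medicated & meals$delivered
  gap <- if (nrow(meals) > 1) min(diff(meals$time_h)) else 24
  n_required <- floor(effect$memory_window_h / gap + 1e-9)
  vapply(times, function(t) {
    idx <- which(meals$time_h > t - effect$memory_window_h &
                   meals$time_h <= t)
    if (length(idx) >= n_required && all(ok[idx]))
      1 - effect$max_reduction else 1
  }, numeric(1))
}
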