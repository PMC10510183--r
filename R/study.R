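#' Generate a complete synthetic adherence study
#'
#' Composes [gen_animals()], [gen_schedule()], [gen_seizures()] and
#' [tdm_sample()] into one reproducible dataset: a cohort split into fully
#' and partially adherent groups, a randomized medication-in-food
#' schedule, a seizure stream per animal under the chosen effect model,
#' and weekly therapeutic drug monitoring samples. All randomness flows
#' from `seed`; the same `(arguments, seed)` pair reproduces the dataset
#' exactly.
#'
#' @param n_full,n_half Group sizes (canonical study: 10 and 12).
#' @param design A [study_design()].
#' @param pk A [pk_params()].
#' @param effect An [effect_model()].
#' @param seed Integer seed for the whole study.
#' @param rate_meanlog,rate_sdlog,cluster_propensity Passed to
#'   [gen_animals()].
#' @param racine_probs Passed to [gen_seizures()].
#' @param tdm Logical, generate weekly plasma samples?
#' @return An object of class `adherence_study`: a list with data frames
#'   `animals`, `meals`, `seizures`, `plasma`, plus `design`, `pk`,
#'   `effect` and `seed`.
#' @examples
#' st <- gen_study(2, 3, seed = 42)
#' nrow(st$meals)   # 5 animals x 224 meals
#' @export
gen_study <- function(n_full = 10, n_half = 12, design = study_design(),
                      pk = pk_params(), effect = effect_model("null"),
                      seed = 1, rate_meanlog = log(5), rate_sdlog = 0.6,
                      cluster_propensity = 0.25,
                      racine_probs = c(0, 0, 1, 1, 1) / 3, tdm = TRUE) {
  stopifnot(inherits(design, "study_design"), inherits(pk, "pk_params"),
            inherits(effect, "effect_model"))
  set.seed(seed)
  animals <- gen_animals(n_full, n_half, rate_meanlog, rate_sdlog,
                         cluster_propensity)
  meals_l <- vector("list", nrow(animals))
  seiz_l <- vector("list", nrow(animals))
  plas_l <- vector("list", nrow(animals))
  for (i in seq_len(nrow(animals))) {
    a <- animals[i, , drop = FALSE]
    m <- gen_schedule(a, design)
    s <- gen_seizures(a, m, pk, effect, racine_probs,
                      span_h = study_span(design))
    meals_l[[i]] <- m
    seiz_l[[i]] <- s
    plas_l[[i]] <- if (tdm) tdm_sample(m, pk, design) else NULL
  }
  structure(list(
    animals = animals,
    meals = do.call(rbind, meals_l),
    seizures = do.call(rbind, seiz_l),
    plasma = if (tdm) do.call(rbind, plas_l) else
      data.frame(animal_id = character(), week = integer(),
                 time_h = numeric(), conc_ng_ml = numeric(),
                 below_lloq = logical()),
    design = design, pk = pk, effect = effect, seed = seed
  ), class = "adherence_study")
}

#' @export
print.adherence_study <- function(x, ...) {
  cat("Synthetic adherence study (seed", x$seed, ")\n")
  cat(sprintf("  animals: %d (%d FULL, %d HALF)\n", nrow(x$animals),
              sum(x$animals$group == "FULL"),
              sum(x$animals$group == "HALF")))
  cat(sprintf("  meals: %d scheduled (%d medicated, %d undelivered)\n",
              nrow(x$meals), sum(x$meals$medicated),
              sum(!x$meals$delivered)))
  cat(sprintf("  seizures: %d scored events; plasma samples: %d\n",
              nrow(x$seizures), nrow(x$plasma)))
  print(x$effect)
  invisible(x)
}

#' Raster plot of meals and seizures
#'
#' One row per animal; medicated meals, placebo meals and seizures drawn
#' along the study time axis, with the baseline/treatment boundary marked.
#'
#' @param x An `adherence_study`.
#' @param max_animals Plot at most this many animals per group.
#' @param ... Unused.
#' @export
plot.adherence_study <- function(x, max_animals = 6, ...) {
  ids <- unlist(lapply(split(x$animals$animal_id, x$animals$group),
                       utils::head, max_animals))
  n <- length(ids)
  graphics::plot(NULL, xlim = c(0, study_span(x$design)),
                 ylim = c(0.5, n + 0.5), xlab = "time (h)",
                 ylab = "", yaxt = "n", main = "Meals and seizures")
  graphics::axis(2, at = seq_len(n), labels = ids, las = 2, cex.axis = 0.7)
  for (i in seq_along(ids)) {
    m <- x$meals[x$meals$animal_id == ids[i], ]
    s <- x$seizures[x$seizures$animal_id == ids[i], ]
    graphics::points(m$time_h, rep(i, nrow(m)), pch = 15, cex = 0.25,
                     col = ifelse(m$medicated, "red", "grey60"))
    if (nrow(s))
      graphics::points(s$time_h, rep(i + 0.3, nrow(s)), pch = 4,
                       cex = 0.5, col = "black")
  }
  graphics::abline(v = treatment_start(x$design), lty = 2)
  invisible(x)
}
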