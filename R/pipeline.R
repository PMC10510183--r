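# FNV-1a 32-bit hash of a character string, reported in hex; used to
# fingerprint configurations in reports without external dependencies.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply in 16-bit limbs to stay within double
    # precision (direct h * p can exceed 2^53)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * p) %% 65536) * 65536 + lo * p
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full simulation and analysis pipeline
#'
#' Chains the generator and every analysis stage into one reproducible
#' run: study generation, enrollment filtering, per-animal normalized
#' seizure-frequency changes and responder summaries per group with a
#' between-group comparison, cluster collapsing, the meal-position
#' table, and the pattern / adherence-level / scenario odds-ratio
#' tables (association analyses use treatment-phase windows of the
#' configured group, HALF by default). Per-stage event counts are logged
#' so attrition is auditable.
#'
#' @param config A [as_run_config()] object or plain named list.
#' @param quiet Suppress per-stage log messages?
#' @return Object of class `adherence_report`: a list with `provenance`
#'   (seed, config hash, package version), `counts` (attrition log),
#'   `responders`, `comparison`, `meal_position`, `patterns`, `levels`,
#'   `scenarios`, and the generated `study`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else as_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulate: %d FULL + %d HALF animals, seed %d", cfg$n_full,
      cfg$n_half, cfg$seed)
  study <- gen_study(cfg$n_full, cfg$n_half, cfg$design, cfg$pk,
                     cfg$effect, seed = cfg$seed,
                     rate_meanlog = cfg$rate_meanlog,
                     rate_sdlog = cfg$rate_sdlog,
                     cluster_propensity = cfg$cluster_propensity)
  say("simulate: %d meals, %d seizures", nrow(study$meals),
      nrow(study$seizures))

  enrolled <- enrollment_filter(study$animals, study$seizures, cfg$design)
  say("enrollment: %d of %d animals meet the baseline criterion",
      length(enrolled), nrow(study$animals))
  animals <- study$animals[study$animals$animal_id %in% enrolled, ]

  t_split <- treatment_start(cfg$design)
  changes <- vapply(animals$animal_id, function(a) {
    s <- study$seizures[study$seizures$animal_id == a, ]
    normalized_change(sum(s$time_h < t_split), sum(s$time_h >= t_split),
                      cfg$design$baseline_weeks,
                      cfg$design$treatment_weeks)
  }, numeric(1))
  by_group <- split(changes, animals$group)
  responders <- lapply(by_group, responder_summary)
  comparison <- if (length(by_group) == 2)
    responder_comparison(by_group$FULL, by_group$HALF) else NULL

  grp <- cfg$analysis$group
  assoc_ids <- animals$animal_id[animals$group == grp]
  meals_g <- study$meals[study$meals$animal_id %in% assoc_ids, ]
  seiz_g <- study$seizures[study$seizures$animal_id %in% assoc_ids, ]
  collapsed <- collapse_clusters(seiz_g, meals_g)
  trt_events <- collapsed[collapsed$time_h >= t_split, ]
  say("association (%s group): %d raw seizures -> %d collapsed events (%d in treatment phase)",
      grp, nrow(seiz_g), nrow(collapsed), nrow(trt_events))

  windows <- adherence_windows(trt_events, meals_g,
                               cfg$design$meals_per_day,
                               cfg$analysis$stride)
  say("association: %d meal-anchored windows (%d with seizure)",
      nrow(windows), sum(windows$seizure))

  report <- structure(list(
    provenance = list(
      seed = cfg$seed,
      config_hash = fnv1a_hash(config_fingerprint(cfg)),
      package_version = as.character(utils::packageVersion("adherogram")),
      effect = cfg$effect$kind
    ),
    counts = list(
      animals = nrow(study$animals), enrolled = length(enrolled),
      meals = nrow(study$meals), seizures = nrow(study$seizures),
      collapsed_events = nrow(collapsed),
      treatment_events = nrow(trt_events), windows = nrow(windows)
    ),
    responders = responders,
    comparison = comparison,
    meal_position = meal_position_table(trt_events, meals_g,
                                        cfg$analysis$max_position,
                                        p0 = cfg$design$adherence_fraction_half),
    patterns = pattern_or_table(trt_events, meals_g,
                                cfg$design$meals_per_day,
                                windows = windows),
    levels = adherence_level_table(trt_events, meals_g,
                                   cfg$design$meals_per_day,
                                   windows = windows),
    scenarios = scenario_table(trt_events, meals_g,
                               cfg$design$meals_per_day,
                               windows = windows),
    study = study
  ), class = "adherence_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_meals(study$meals, file.path(cfg$output_dir, "meals.csv"))
    write_seizures(study$seizures,
                   file.path(cfg$output_dir, "seizures.csv"))
    write_plasma(study$plasma[, c("animal_id", "time_h", "conc_ng_ml")],
                 file.path(cfg$output_dir, "plasma.csv"))
    write_report(report, file.path(cfg$output_dir, "report.json"))
  }
  report
}

# Canonical text fingerprint of a run configuration (the output location
# is not part of the scientific content and is excluded).
config_fingerprint <- function(cfg) {
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  paste(readLines(tmp, warn = FALSE), collapse = "")
}

#' Serialize a pipeline report to JSON
#'
#' Writes the report's tables and provenance (not the raw study data) as
#' a JSON bundle mirroring the structure of the summary tables: group
#' responder summaries, the per-meal-position distribution, and the
#' pattern / level / scenario odds-ratio tables.
#'
#' @param report An `adherence_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "adherence_report"))
  strip <- function(df) as.data.frame(unclass(df), stringsAsFactors = FALSE)
  resp <- lapply(report$responders, function(r)
    r[c("n", "median_pct", "median_ci95", "responders_25",
        "responders_50", "seizure_free")])
  out <- list(
    provenance = report$provenance,
    counts = report$counts,
    responders = resp,
    meal_position = strip(report$meal_position),
    patterns = strip(report$patterns),
    levels = strip(report$levels),
    scenarios = strip(report$scenarios)
  )
  if (!is.null(report$comparison))
    out$comparison <- list(
      mann_whitney_p = report$comparison$mann_whitney$p.value,
      fisher_responders_p = report$comparison$fisher_responders$p.value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("Adherence pipeline report\n")
  cat(sprintf("  seed %d, config %s, effect %s\n", x$provenance$seed,
              x$provenance$config_hash, x$provenance$effect))
  cat(sprintf("  %d animals (%d enrolled), %d meals, %d seizures -> %d collapsed (%d treatment-phase), %d windows\n",
              x$counts$animals, x$counts$enrolled, x$counts$meals,
              x$counts$seizures, x$counts$collapsed_events,
              x$counts$treatment_events, x$counts$windows))
  for (g in names(x$responders)) {
    cat(sprintf("-- %s group --\n", g))
    print(x$responders[[g]])
  }
  if (!is.null(x$comparison))
    cat(sprintf("  between-group Mann-Whitney p = %.4g; Fisher responder p = %.4g\n",
                x$comparison$mann_whitney$p.value,
                x$comparison$fisher_responders$p.value))
  print(x$meal_position)
  print(x$patterns)
  invisible(x)
}
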