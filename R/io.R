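#' Event-log CSV input/output
#'
#' Readers validate the declared header and reject malformed rows with
#' their line numbers; writers produce plain CSV that round-trips
#' losslessly (order preserved).
#'
#' Formats:
#' * meals: `animal_id, time_h, phase, medicated, delivered,
#'   dose_mg_per_kg`
#' * seizures: `animal_id, time_h, racine`
#' * plasma: `animal_id, time_h, conc_ng_ml`
#'
#' @param path File path.
#' @param meals,seizures,plasma Data frames as produced by the
#'   generators.
#' @return Readers return validated data frames; writers return the path
#'   invisibly.
#' @name event_io
NULL

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " is missing required columns: ",
         paste(missing, collapse = ", "))
}

# data rows start at line 2 (after the header)
bad_rows <- function(cond) which(cond) + 1L

as_flag <- function(x, name, path) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- ifelse(v %in% c("TRUE", "T", "1"), TRUE,
                ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
  if (anyNA(out))
    stop("file ", path, ": column ", name,
         " must be boolean; offending lines: ",
         paste(bad_rows(is.na(out)), collapse = ", "))
  out
}

#' @rdname event_io
#' @export
read_meals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("animal_id", "time_h", "phase", "medicated",
                      "delivered", "dose_mg_per_kg"), path)
  if (!is.numeric(df$time_h) || anyNA(df$time_h) || any(df$time_h < 0))
    stop("file ", path, ": time_h must be numeric and non-negative",
         if (anyNA(df$time_h) || any(df$time_h < 0, na.rm = TRUE))
           paste0("; offending lines: ",
                  paste(bad_rows(is.na(df$time_h) | df$time_h < 0),
                        collapse = ", ")))
  bad_phase <- !(df$phase %in% c("BASELINE", "TREATMENT"))
  if (any(bad_phase))
    stop("file ", path, ": phase must be BASELINE or TREATMENT; ",
         "offending lines: ", paste(bad_rows(bad_phase), collapse = ", "))
  df$medicated <- as_flag(df$medicated, "medicated", path)
  df$delivered <- as_flag(df$delivered, "delivered", path)
  if (!is.numeric(df$dose_mg_per_kg) || any(df$dose_mg_per_kg < 0))
    stop("file ", path, ": dose_mg_per_kg must be numeric, non-negative")
  df
}

#' @rdname event_io
#' @export
write_meals <- function(meals, path) {
  utils::write.csv(meals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname event_io
#' @export
read_seizures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("animal_id", "time_h", "racine"), path)
  if (!is.numeric(df$time_h) || anyNA(df$time_h) || any(df$time_h < 0))
    stop("file ", path, ": time_h must be numeric and non-negative")
  bad <- is.na(df$racine) | df$racine != round(df$racine) |
    df$racine < 1 | df$racine > 5
  if (any(bad))
    stop("file ", path, ": racine must be an integer in 1..5; ",
         "offending lines: ", paste(bad_rows(bad), collapse = ", "))
  df$racine <- as.integer(df$racine)
  df
}

#' @rdname event_io
#' @export
write_seizures <- function(seizures, path) {
  utils::write.csv(seizures, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname event_io
#' @export
read_plasma <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("animal_id", "time_h", "conc_ng_ml"), path)
  if (any(df$conc_ng_ml < 0, na.rm = TRUE))
    stop("file ", path, ": conc_ng_ml must be non-negative")
  df
}

#' @rdname event_io
#' @export
write_plasma <- function(plasma, path) {
  utils::write.csv(plasma, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_config_known_keys <- c("n_full", "n_half", "seed", "design", "pk",
                           "effect", "output_dir", "analysis",
                           "rate_meanlog", "rate_sdlog",
                           "cluster_propensity")

#' Run configuration for the end-to-end pipeline
#'
#' Builds (or validates) the configuration consumed by
#' [run_pipeline()]: group sizes, seed, [study_design()], [pk_params()],
#' [effect_model()] and analysis flags. Unknown keys are rejected so a
#' mistyped option cannot silently alter a run. Configurations
#' round-trip losslessly through JSON (and YAML, if the yaml package is
#' available).
#'
#' @param config Named list with any of: `n_full`, `n_half`, `seed`,
#'   `design` (list of [study_design()] arguments), `pk`, `effect`,
#'   `rate_meanlog`, `rate_sdlog`, `cluster_propensity`, `output_dir`,
#'   `analysis` (list: `group`, `max_position`, `stride`).
#' @return Object of class `run_config`.
#' @export
as_run_config <- function(config = list()) {
  unknown <- setdiff(names(config), run_config_known_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  analysis_known <- c("group", "max_position", "stride")
  if (!is.null(config$analysis)) {
    bad <- setdiff(names(config$analysis), analysis_known)
    if (length(bad))
      stop("unknown analysis keys: ", paste(bad, collapse = ", "))
  }
  cfg <- list(
    n_full = config$n_full %||% 10L,
    n_half = config$n_half %||% 12L,
    seed = config$seed %||% 1L,
    design = do.call(study_design, as.list(config$design)),
    pk = do.call(pk_params, as.list(config$pk)),
    effect = do.call(effect_model, as.list(config$effect)),
    rate_meanlog = config$rate_meanlog %||% log(5),
    rate_sdlog = config$rate_sdlog %||% 0.6,
    cluster_propensity = config$cluster_propensity %||% 0.25,
    output_dir = config$output_dir,
    analysis = list(
      group = config$analysis$group %||% "HALF",
      max_position = config$analysis$max_position %||% 10L,
      stride = config$analysis$stride %||% 1L
    )
  )
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname as_run_config
#' @param path Path to a `.json` or `.yaml`/`.yml` configuration file.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_run_config(raw)
}

#' @rdname as_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- list(
    n_full = cfg$n_full, n_half = cfg$n_half, seed = cfg$seed,
    design = unclass(cfg$design)[setdiff(names(cfg$design), "inter_meal_h")],
    pk = unclass(cfg$pk)[c("half_life_h", "ka_per_h", "scale",
                           "lloq_ng_ml")],
    effect = unclass(cfg$effect),
    rate_meanlog = cfg$rate_meanlog, rate_sdlog = cfg$rate_sdlog,
    cluster_propensity = cfg$cluster_propensity,
    analysis = cfg$analysis
  )
  if (!is.null(cfg$output_dir)) plain$output_dir <- cfg$output_dir
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
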