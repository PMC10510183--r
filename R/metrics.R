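#' Enrollment filter on baseline seizure frequency
#'
#' Keeps animals whose baseline-phase frequency of convulsive seizures
#' (Racine stage `min_racine` or higher) averages at least `min_rate` per
#' week. Animals with no baseline seizure data are excluded with a
#' warning.
#'
#' @param animals Animal data frame ([gen_animals()]).
#' @param seizures Seizure event data frame.
#' @param design A [study_design()] (defines the baseline phase).
#' @param min_rate Required weekly rate (default 1 per week).
#' @param min_racine Minimum Racine stage counted (default 3).
#' @param strict If `TRUE`, require strictly greater than `min_rate`;
#'   default is the inclusive criterion (>=).
#' @return Character vector of enrolled `animal_id`s.
#' @export
enrollment_filter <- function(animals, seizures, design = study_design(),
                              min_rate = 1, min_racine = 3,
                              strict = FALSE) {
  t_end <- treatment_start(design)
  base <- seizures[seizures$time_h < t_end & seizures$racine >= min_racine, ]
  counts <- table(factor(base$animal_id, levels = animals$animal_id))
  weekly <- as.numeric(counts) / design$baseline_weeks
  keep <- if (strict) weekly > min_rate else weekly >= min_rate
  none <- animals$animal_id[!(animals$animal_id %in% seizures$animal_id)]
  if (length(none))
    warning("no baseline seizure data for: ", paste(none, collapse = ", "))
  animals$animal_id[keep]
}

#' Collapse seizure clusters to one event per inter-meal interval
#'
#' Multiple seizures falling in the same half-open inter-meal interval
#' `[t_i, t_{i+1})` of an animal's schedule are merged into a single
#' collapsed event, so that association analyses weight each meal pattern
#' once regardless of cluster size. The collapsed event keeps the time of
#' its first seizure and the maximum Racine score of its members.
#'
#' Seizures occurring before an animal's first meal are assigned
#' `interval_index = 0` and flagged `pre_study`.
#'
#' @param seizures Seizure event data frame.
#' @param meals Meal event data frame (defines per-animal interval grids).
#' @return Data frame of class `collapsed_events`: `animal_id`,
#'   `interval_index` (1-based index of the meal opening the interval),
#'   `time_h`, `max_racine`, `n_raw`, `pre_study`; sorted by animal and
#'   time. Collapsing is idempotent.
#' @export
collapse_clusters <- function(seizures, meals) {
  # accept already-collapsed events so that collapsing is idempotent
  if (!"racine" %in% names(seizures) && "max_racine" %in% names(seizures))
    seizures$racine <- seizures$max_racine
  out <- lapply(split(seizures, seizures$animal_id), function(s) {
    mt <- sort(meals$time_h[meals$animal_id == s$animal_id[1]])
    if (length(mt) == 0)
      stop("no meals for animal ", s$animal_id[1])
    idx <- findInterval(s$time_h, mt)
    agg <- lapply(split(seq_len(nrow(s)), idx), function(i) {
      data.frame(animal_id = s$animal_id[1],
                 interval_index = idx[i[1]],
                 time_h = min(s$time_h[i]),
                 max_racine = max(s$racine[i]),
                 n_raw = if ("n_raw" %in% names(s)) sum(s$n_raw[i])
                         else length(i),
                 pre_study = idx[i[1]] == 0,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(animal_id = character(), interval_index = integer(),
                      time_h = numeric(), max_racine = integer(),
                      n_raw = integer(), pre_study = logical(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$animal_id, res$time_h), ]
  rownames(res) <- NULL
  class(res) <- c("collapsed_events", "data.frame")
  res
}

#' Seizure burden in a time window
#'
#' Burden is the plain sum of Racine scores of raw (uncollapsed) seizures
#' with `time_h` in the half-open window `[from, to)`. It is additive
#' over disjoint windows.
#'
#' @param seizures Seizure event data frame (optionally one animal's).
#' @param from,to Window bounds in hours.
#' @return Total burden (numeric scalar).
#' @examples
#' s <- data.frame(animal_id = "a", time_h = c(1, 2, 3), racine = c(3, 4, 5))
#' seizure_burden(s, 0, 10)   # 12
#' @export
seizure_burden <- function(seizures, from = -Inf, to = Inf) {
  sum(seizures$racine[seizures$time_h >= from & seizures$time_h < to])
}

#' Cumulative seizure burden by recording epoch
#'
#' @param seizures Seizure event data frame.
#' @param span_h Total span to cover, hours.
#' @param epoch_h Epoch width, hours (recording systems typically store
#'   12-h epochs).
#' @return Data frame with `epoch_end_h` and the nondecreasing
#'   `cumulative_burden` reaching the total burden at `span_h`.
#' @export
cumulative_burden <- function(seizures, span_h, epoch_h = 12) {
  ends <- seq(epoch_h, span_h, by = epoch_h)
  if (ends[length(ends)] < span_h) ends <- c(ends, span_h)
  cb <- vapply(ends, function(e) seizure_burden(seizures, -Inf, e),
               numeric(1))
  data.frame(epoch_end_h = ends, cumulative_burden = cb)
}

#' Percent change in seizure rate relative to baseline
#'
#' `100 * (treatment_rate - baseline_rate) / baseline_rate` with rates
#' expressed per week, so each animal is normalized to its own baseline.
#' Equal-duration phases make this identical to the percent change in raw
#' counts. `-100` means seizure freedom.
#'
#' @param baseline_count,treatment_count Seizure counts in each phase
#'   (vectorized).
#' @param baseline_weeks,treatment_weeks Phase durations in weeks.
#' @return Percent change (numeric, possibly vector). Zero baseline gives
#'   `NA` with a warning (cannot occur after enrollment filtering).
#' @examples
#' normalized_change(8, 4, 4, 4)   # -50
#' @export
normalized_change <- function(baseline_count, treatment_count,
                              baseline_weeks = 4, treatment_weeks = 4) {
  stopifnot(baseline_weeks > 0, treatment_weeks > 0)
  br <- baseline_count / baseline_weeks
  tr <- treatment_count / treatment_weeks
  out <- 100 * (tr - br) / br
  if (any(br == 0)) {
    warning("zero baseline count: percent change undefined, returning NA")
    out[br == 0] <- NA_real_
  }
  out
}

# Distribution-free CI for the median via binomial order statistics:
# the widest symmetric pair of order statistics whose binomial coverage
# is at least `level`.
median_ci_orderstat <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  if (n < 2) return(c(lower = x[1], upper = x[n]))
  alpha <- (1 - level) / 2
  l <- stats::qbinom(alpha, n, 0.5)
  # qbinom gives smallest l with pbinom(l) >= alpha; step down until the
  # lower tail is truly <= alpha to guarantee >= level coverage
  while (l > 0 && stats::pbinom(l - 1, n, 0.5) > alpha) l <- l - 1
  if (l < 1) return(c(lower = x[1], upper = x[n]))
  c(lower = x[l], upper = x[n + 1 - l])
}

#' Responder summary of per-animal percent changes
#'
#' Counts responders at the conventional thresholds — more than 25% and
#' more than 50% reduction in seizure frequency (i.e. change strictly
#' below -25 / -50), and seizure freedom (change of exactly -100) — and
#' reports the median change with a distribution-free 95% CI from
#' binomial order statistics.
#'
#' @param changes Numeric vector of per-animal percent changes
#'   ([normalized_change()]).
#' @param level Confidence level for the median CI.
#' @return Object of class `responder_summary`.
#' @examples
#' responder_summary(c(-100, -100, -100, -60, -55, 10, 20, 30, 40, 50))
#' @export
responder_summary <- function(changes, level = 0.95) {
  changes <- changes[!is.na(changes)]
  if (length(changes) == 0) stop("no (non-missing) changes supplied")
  if (any(changes < -100)) stop("percent change cannot fall below -100")
  structure(list(
    n = length(changes),
    per_animal_pct_change = changes,
    median_pct = stats::median(changes),
    median_ci95 = median_ci_orderstat(changes, level),
    responders_25 = sum(changes < -25),
    responders_50 = sum(changes < -50),
    seizure_free = sum(changes == -100)
  ), class = "responder_summary")
}

#' @export
print.responder_summary <- function(x, ...) {
  cat("Responder summary (n =", x$n, ")\n")
  cat(sprintf("  median change: %+.1f%% [%.1f, %.1f]\n", x$median_pct,
              x$median_ci95[1], x$median_ci95[2]))
  cat(sprintf("  >25%% responders: %d/%d   >50%% responders: %d/%d   seizure-free: %d/%d\n",
              x$responders_25, x$n, x$responders_50, x$n,
              x$seizure_free, x$n))
  invisible(x)
}

#' Compare two groups' seizure outcomes
#'
#' Between-group comparison of baseline-normalized percent changes via
#' the two-tailed Mann-Whitney test, and of the >50% responder rates via
#' the Fisher exact test.
#'
#' @param changes_a,changes_b Percent-change vectors for the two groups.
#' @return List with both group [responder_summary()]s, the Mann-Whitney
#'   `htest` and the Fisher `htest` on the 2x2 responder table.
#' @export
responder_comparison <- function(changes_a, changes_b) {
  sa <- responder_summary(changes_a)
  sb <- responder_summary(changes_b)
  list(
    group_a = sa, group_b = sb,
    mann_whitney = mann_whitney_u(changes_a, changes_b),
    fisher_responders = fisher_exact_2x2(
      sa$responders_50, sa$n - sa$responders_50,
      sb$responders_50, sb$n - sb$responders_50)
  )
}
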