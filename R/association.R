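#' Distribution of medicated meals at each position before a seizure
#'
#' For every collapsed seizure event and each position `k = 1..max_position`,
#' looks up the k-th meal counting backwards from the event (position 1 is
#' the meal opening the inter-meal interval that contains the event) and
#' tallies whether it was medicated and delivered. Counts are pooled
#' across animals and compared position-by-position to the null
#' expectation `p0` (the scheduled adherence fraction, 0.5 by default)
#' with an exact two-tailed binomial test; confidence intervals are
#' Wilson score intervals.
#'
#' Positions whose looked-up meal falls outside the treatment phase (or
#' before the schedule starts) are excluded from that position's
#' denominator, since baseline meals are placebo by design.
#'
#' @param collapsed Collapsed events ([collapse_clusters()]).
#' @param meals Meal event data frame for the same animals.
#' @param max_position Number of preceding meals tabulated.
#' @param p0 Null probability that a meal is medicated.
#' @param restrict_phase Phase a looked-up meal must belong to
#'   (`"TREATMENT"` default; `NULL` disables the restriction).
#' @return Data frame of class `meal_position_table`: one row per
#'   position with `n_events`, `n_medicated`, `pct_medicated`,
#'   `ci_lower`, `ci_upper` (percent scale) and `p_two_tailed`.
#' @export
meal_position_table <- function(collapsed, meals, max_position = 10,
                                p0 = 0.5, restrict_phase = "TREATMENT") {
  stopifnot(max_position >= 1, nrow(collapsed) > 0)
  n_events <- integer(max_position)
  n_med <- integer(max_position)
  for (a in unique(collapsed$animal_id)) {
    m <- meals[meals$animal_id == a, ]
    m <- m[order(m$time_h), ]
    ok <- m$medicated & m$delivered
    in_phase <- if (is.null(restrict_phase)) rep(TRUE, nrow(m))
                else m$phase == restrict_phase
    ev <- collapsed[collapsed$animal_id == a & !collapsed$pre_study, ]
    for (i in ev$interval_index) {
      for (k in seq_len(max_position)) {
        j <- i - k + 1
        if (j >= 1 && in_phase[j]) {
          n_events[k] <- n_events[k] + 1L
          if (ok[j]) n_med[k] <- n_med[k] + 1L
        }
      }
    }
  }
  ci <- t(vapply(seq_len(max_position), function(k) {
    if (n_events[k] == 0) c(NA_real_, NA_real_)
    else wilson_ci(n_med[k], n_events[k])
  }, numeric(2)))
  pv <- vapply(seq_len(max_position), function(k) {
    if (n_events[k] == 0) NA_real_
    else binom_test_two_tailed(n_med[k], n_events[k], p0)$p.value
  }, numeric(1))
  out <- data.frame(
    position = seq_len(max_position),
    n_events = n_events, n_medicated = n_med,
    pct_medicated = ifelse(n_events > 0, 100 * n_med / n_events, NA_real_),
    ci_lower = 100 * ci[, 1], ci_upper = 100 * ci[, 2],
    p_two_tailed = pv
  )
  attr(out, "p0") <- p0
  class(out) <- c("meal_position_table", "data.frame")
  out
}

#' @export
print.meal_position_table <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Medicated-meal distribution before seizures (expected %.0f%%)\n",
    100 * attr(x, "p0")))
  print.data.frame(
    data.frame(position = x$position, n = x$n_events,
               observed_pct = round(x$pct_medicated, 1),
               ci95 = sprintf("[%4.1f, %4.1f]", x$ci_lower, x$ci_upper),
               p = signif(x$p_two_tailed, digits)),
    row.names = FALSE)
  invisible(x)
}

#' Enumerate the possible 24-h medication-delivery patterns
#'
#' With `k` meals per day there are `2^k` distinct adherence patterns in
#' a 24-h window, from completely nonadherent to fully adherent. Patterns
#' are listed in binary ascending order with the oldest meal as the most
#' significant bit.
#'
#' @param meals_per_day Meals per 24 h (at most 16).
#' @return Data frame with `pattern_id` (0-based), `pattern` (bit string,
#'   oldest meal first, `1` = medicated) and `n_medicated`.
#' @examples
#' nrow(enumerate_patterns(4))   # 16
#' @export
enumerate_patterns <- function(meals_per_day = 4) {
  if (meals_per_day < 1) stop("meals_per_day must be >= 1")
  if (meals_per_day > 16) stop("refusing to enumerate more than 2^16 patterns")
  ids <- 0:(2^meals_per_day - 1)
  bits <- t(vapply(ids, function(i)
    as.integer(intToBits(i))[meals_per_day:1], integer(meals_per_day)))
  data.frame(
    pattern_id = ids,
    pattern = apply(bits, 1, paste, collapse = ""),
    n_medicated = rowSums(bits)
  )
}

#' Meal-anchored adherence windows with seizure outcome
#'
#' Internal engine for the odds-ratio analyses. For every meal slot `m`
#' with at least `meals_per_day - 1` preceding meals, the window is the
#' medication pattern (medicated and delivered) of the `meals_per_day`
#' meals ending at `m`, and the outcome is whether at least one collapsed
#' event falls in the inter-meal interval opened by meal `m`. By default
#' all window meals must lie in the treatment phase, and consecutive
#' windows overlap (`stride = 1`).
#'
#' @param collapsed Collapsed events.
#' @param meals Meal event data frame.
#' @param meals_per_day Window width in meals.
#' @param stride Step between consecutive window anchors (in meal slots);
#'   `meals_per_day` gives non-overlapping windows.
#' @param restrict_phase Phase all window meals must belong to (`NULL`
#'   disables).
#' @return Data frame with one row per window: `animal_id`,
#'   `pattern_id`, `seizure` (logical).
#' @keywords internal
#' @export
adherence_windows <- function(collapsed, meals, meals_per_day = 4,
                              stride = 1, restrict_phase = "TREATMENT") {
  stopifnot(meals_per_day >= 1, stride >= 1)
  weights <- 2^((meals_per_day - 1):0)   # oldest meal = most significant
  out <- lapply(unique(meals$animal_id), function(a) {
    m <- meals[meals$animal_id == a, ]
    m <- m[order(m$time_h), ]
    bits <- as.integer(m$medicated & m$delivered)
    in_phase <- if (is.null(restrict_phase)) rep(TRUE, nrow(m))
                else m$phase == restrict_phase
    ev_idx <- collapsed$interval_index[collapsed$animal_id == a &
                                         !collapsed$pre_study]
    anchors <- seq(meals_per_day, nrow(m), by = stride)
    keep <- vapply(anchors, function(mm)
      all(in_phase[(mm - meals_per_day + 1):mm]), logical(1))
    anchors <- anchors[keep]
    if (length(anchors) == 0) return(NULL)
    data.frame(
      animal_id = a,
      anchor = anchors,
      pattern_id = vapply(anchors, function(mm)
        sum(bits[(mm - meals_per_day + 1):mm] * weights), numeric(1)),
      seizure = anchors %in% ev_idx,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("no adherence windows could be constructed")
  res
}

# Shared builder: 2x2 table + OR per level of a window classification.
or_table_from_windows <- function(windows, class_id, labels, extra = NULL) {
  n_seiz <- sum(windows$seizure)
  n_tot <- nrow(windows)
  rows <- lapply(seq_along(labels), function(i) {
    in_cls <- class_id == i
    a <- sum(windows$seizure[in_cls])
    b <- sum(in_cls) - a
    c <- n_seiz - a
    d <- (n_tot - sum(in_cls)) - c
    if (sum(in_cls) == 0 || sum(in_cls) == n_tot)
      return(data.frame(label = labels[i], a = a, b = b, c = c, d = d,
                        or = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, z = NA_real_, p = NA_real_))
    o <- odds_ratio_2x2(a, b, c, d)
    data.frame(label = labels[i], a = a, b = b, c = c, d = d,
               or = unname(o$estimate), ci_lower = o$conf.int[1],
               ci_upper = o$conf.int[2], z = unname(o$statistic),
               p = o$p.value)
  })
  out <- do.call(rbind, rows)
  if (!is.null(extra)) out <- cbind(extra, out)
  attr(out, "n_windows") <- n_tot
  attr(out, "n_seizure_windows") <- n_seiz
  class(out) <- c("pattern_or_table", "data.frame")
  out
}

#' Odds ratio of seizure incidence for each 24-h adherence pattern
#'
#' For every one of the `2^meals_per_day` medication-delivery patterns,
#' builds the 2x2 table of meal-anchored windows (pattern vs all other
#' patterns, seizure in the following inter-meal interval vs none) and
#' reports the odds ratio with Wald 95% CI, Wald z and chi-square p
#' (Haldane-Anscombe 0.5 correction when a cell is empty). A confidence
#' interval excluding 1 flags a pattern associated with raised or
#' lowered seizure incidence.
#'
#' @inheritParams adherence_windows
#' @param windows Optionally, precomputed [adherence_windows()].
#' @param mode `"cohort"` (default) scores every window against all other
#'   windows; `"case_only"` compares, per pattern, its frequency among
#'   seizure-preceding windows to its frequency among all windows via an
#'   exact binomial test (the odds ratio reported is the ratio of
#'   observed to expected pattern odds among cases).
#' @return Data frame of class `pattern_or_table`, one row per pattern.
#' @export
pattern_or_table <- function(collapsed, meals, meals_per_day = 4,
                             stride = 1, restrict_phase = "TREATMENT",
                             windows = NULL,
                             mode = c("cohort", "case_only")) {
  mode <- match.arg(mode)
  if (is.null(windows))
    windows <- adherence_windows(collapsed, meals, meals_per_day, stride,
                                 restrict_phase)
  pats <- enumerate_patterns(meals_per_day)
  if (mode == "case_only") {
    cases <- windows[windows$seizure, ]
    if (nrow(cases) == 0) stop("no seizure-preceding windows")
    rows <- lapply(seq_len(nrow(pats)), function(i) {
      k <- sum(cases$pattern_id == pats$pattern_id[i])
      n <- nrow(cases)
      p_exp <- mean(windows$pattern_id == pats$pattern_id[i])
      if (p_exp == 0 || p_exp == 1)
        return(data.frame(pattern_id = pats$pattern_id[i],
                          label = pats$pattern[i], a = k, b = n - k,
                          c = NA, d = NA, or = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          z = NA_real_, p = NA_real_))
      obs_odds <- (k + 0.5) / (n - k + 0.5)
      exp_odds <- p_exp / (1 - p_exp)
      ci <- wilson_ci(k, n)
      data.frame(pattern_id = pats$pattern_id[i], label = pats$pattern[i],
                 a = k, b = n - k, c = NA, d = NA,
                 or = obs_odds / exp_odds,
                 ci_lower = (ci[1] / (1 - ci[1])) / exp_odds,
                 ci_upper = (ci[2] / (1 - ci[2])) / exp_odds,
                 z = NA_real_,
                 p = binom_test_two_tailed(k, n, p_exp)$p.value)
    })
    out <- do.call(rbind, rows)
    attr(out, "n_windows") <- nrow(windows)
    attr(out, "n_seizure_windows") <- nrow(cases)
    class(out) <- c("pattern_or_table", "data.frame")
    return(out)
  }
  cls <- match(windows$pattern_id, pats$pattern_id)
  or_table_from_windows(windows, cls, pats$pattern,
                        extra = pats["pattern_id"])
}

#' Odds ratios for grouped acute adherence levels
#'
#' Groups the 24-h windows by their medicated-meal count expressed as a
#' percent adherence level (0, 25, 50, 75, 100% under q.i.d. dosing) and
#' computes each level's odds ratio against all other windows.
#'
#' @inheritParams pattern_or_table
#' @return A `pattern_or_table` with one row per adherence level.
#' @export
adherence_level_table <- function(collapsed, meals, meals_per_day = 4,
                                  stride = 1,
                                  restrict_phase = "TREATMENT",
                                  windows = NULL) {
  if (is.null(windows))
    windows <- adherence_windows(collapsed, meals, meals_per_day, stride,
                                 restrict_phase)
  pats <- enumerate_patterns(meals_per_day)
  n_med <- pats$n_medicated[match(windows$pattern_id, pats$pattern_id)]
  levels_pct <- round(100 * (0:meals_per_day) / meals_per_day)
  cls <- n_med + 1L
  or_table_from_windows(windows, cls, sprintf("%d%%", levels_pct))
}

#' Built-in nonadherence scenario predicates
#'
#' Named predicates over a 24-h pattern (logical vector, oldest meal
#' first, `TRUE` = medicated) describing clinically motivated scenarios:
#' missing the final 1-3 doses before the outcome interval, any run of
#' two or more consecutive missed doses, a fully missed day, and full
#' adherence.
#'
#' @return Named list of predicate functions.
#' @export
default_scenarios <- function() {
  run_missed <- function(bits, len) {
    r <- rle(!bits)
    any(r$values & r$lengths >= len)
  }
  list(
    "all missed" = function(bits) !any(bits),
    "full adherence" = function(bits) all(bits),
    ">=2 consecutive missed" = function(bits) run_missed(bits, 2),
    "final dose missed" = function(bits) !bits[length(bits)],
    "final 2 missed" = function(bits) !any(bits[(length(bits) - 1):length(bits)]),
    "final 3 missed" = function(bits) !any(bits[(length(bits) - 2):length(bits)])
  )
}

#' Odds ratios for nonadherence scenarios
#'
#' Evaluates each scenario predicate over the pattern of every 24-h
#' window and computes the odds ratio of seizure incidence for windows
#' matching the scenario versus its complement. Scenarios matching no
#' windows are reported with `NA` odds ratios.
#'
#' @inheritParams pattern_or_table
#' @param scenarios Named list of predicates over a logical pattern
#'   vector (oldest meal first); see [default_scenarios()].
#' @return A `pattern_or_table` with one row per scenario.
#' @export
scenario_table <- function(collapsed, meals, meals_per_day = 4,
                           scenarios = default_scenarios(), stride = 1,
                           restrict_phase = "TREATMENT", windows = NULL) {
  if (is.null(windows))
    windows <- adherence_windows(collapsed, meals, meals_per_day, stride,
                                 restrict_phase)
  pats <- enumerate_patterns(meals_per_day)
  pat_bits <- lapply(strsplit(pats$pattern, ""), function(ch) ch == "1")
  rows <- lapply(seq_along(scenarios), function(i) {
    match_ids <- pats$pattern_id[vapply(pat_bits, scenarios[[i]],
                                        logical(1))]
    in_cls <- windows$pattern_id %in% match_ids
    w <- windows
    cls <- ifelse(in_cls, 1L, 2L)
    tab <- or_table_from_windows(w, cls, c(names(scenarios)[i], "other"))
    tab[1, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  attr(out, "n_windows") <- nrow(windows)
  attr(out, "n_seizure_windows") <- sum(windows$seizure)
  class(out) <- c("pattern_or_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' @export
print.pattern_or_table <- function(x, digits = 3, ...) {
  cat(sprintf("Adherence-pattern odds ratios (%d windows, %d with seizure)\n",
              attr(x, "n_windows"), attr(x, "n_seizure_windows")))
  df <- data.frame(
    pattern = x$label, "windows" = x$a + x$b, "w/seizure" = x$a,
    OR = round(x$or, digits),
    ci95 = ifelse(is.na(x$or), "-",
                  sprintf("[%.*f, %.*f]", digits, x$ci_lower, digits,
                          x$ci_upper)),
    p = signif(x$p, digits), check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Forest-style plot of an odds-ratio table
#'
#' @param x A `pattern_or_table`.
#' @param ... Unused.
#' @export
plot.pattern_or_table <- function(x, ...) {
  ok <- !is.na(x$or)
  n <- sum(ok)
  graphics::plot(NULL, xlim = range(c(x$ci_lower[ok], x$ci_upper[ok], 1)),
                 ylim = c(0.5, n + 0.5), log = "x",
                 xlab = "odds ratio (log scale)", ylab = "",
                 yaxt = "n", main = "Seizure odds by adherence pattern")
  graphics::axis(2, at = seq_len(n), labels = x$label[ok], las = 2,
                 cex.axis = 0.7)
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::segments(x$ci_lower[ok], seq_len(n), x$ci_upper[ok], seq_len(n))
  graphics::points(x$or[ok], seq_len(n), pch = 16)
  invisible(x)
}
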