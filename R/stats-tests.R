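#' Exact two-tailed binomial test
#'
#' Tests `k` successes in `n` trials against success probability `p0`.
#' The two-tailed p-value follows the minimum-likelihood ("minlike")
#' convention: the sum of binomial point probabilities not exceeding that
#' of the observed count. A doubled-one-tail convention is available via
#' `convention = "doubled"`.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @param convention `"minlike"` (default) or `"doubled"`.
#' @return An object of class `htest` with the observed count, `n`, the
#'   estimated proportion and the two-tailed p-value.
#' @examples
#' binom_test_two_tailed(103, 206, 0.5)$p.value   # 1 by symmetry
#' @export
binom_test_two_tailed <- function(k, n, p0 = 0.5,
                                  convention = c("minlike", "doubled")) {
  convention <- match.arg(convention)
  if (length(k) != 1 || length(n) != 1 || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n))
    stop("require integers 0 <= k <= n, n >= 1")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  d <- stats::dbinom(0:n, n, p0)
  p <- if (convention == "minlike") {
    # relative tolerance guards against ties broken by floating point
    sum(d[d <= d[k + 1] * (1 + 1e-7)])
  } else {
    2 * min(stats::pbinom(k, n, p0),
            stats::pbinom(k - 1, n, p0, lower.tail = FALSE))
  }
  structure(list(
    statistic = c(k = k), parameter = c(n = n),
    estimate = c(proportion = k / n), null.value = c(p = p0),
    p.value = min(1, p), alternative = "two.sided",
    method = sprintf("Exact two-tailed binomial test (%s)", convention),
    data.name = sprintf("%d successes in %d trials", k, n)
  ), class = "htest")
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Successes.
#' @param n Trials (must be positive).
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be positive")
  if (k < 0 || k > n) stop("require 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  centre <- (ph + z^2 / (2 * n)) / den
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Odds ratio for a 2x2 table with Wald confidence interval
#'
#' Computes `OR = (a d)/(b c)`. When any cell is zero, the
#' Haldane-Anscombe correction adds 0.5 to every cell before computing
#' the odds ratio and its standard error. The confidence interval is Wald
#' on the log odds ratio; `z = log(OR)/SE`. The p-value is from the
#' Pearson chi-square statistic (1 df) of the uncorrected table (Yates
#' continuity correction available via `yates = TRUE`).
#'
#' @param a,b,c,d Cell counts: rows = exposed/unexposed, columns =
#'   event/no event, so `a` = exposed with event.
#' @param level Confidence level for the interval.
#' @param yates Apply Yates continuity correction to the chi-square?
#' @return An `htest`-classed list with elements `estimate` (the odds
#'   ratio), `conf.int`, `statistic` (`z`), `chisq` and `p.value`.
#' @examples
#' odds_ratio_2x2(5, 95, 20, 80)$estimate   # 0.2105
#' @export
odds_ratio_2x2 <- function(a, b, c, d, level = 0.95, yates = FALSE) {
  cells <- as.numeric(c(a, b, c, d))   # doubles: dev^2 overflows integers
  if (any(cells < 0)) stop("cell counts must be non-negative")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  if (a + b == 0 || c + d == 0)
    stop("odds ratio undefined: an exposure row has no observations")
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  z <- log(or) / se
  zc <- stats::qnorm(1 - (1 - level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zc * se)
  # Pearson chi-square on the original table
  nn <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (c1 == 0 || c2 == 0) {
    chisq <- 0; p <- 1
  } else {
    dev <- abs(a * d - b * c)
    if (yates) dev <- max(0, dev - nn / 2)
    chisq <- nn * dev^2 / (r1 * r2 * c1 * c2)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  out <- list(
    statistic = c(z = z), chisq = c("X-squared" = chisq),
    estimate = c("odds ratio" = or), conf.int = ci, p.value = p,
    corrected = any(cells == 0), alternative = "two.sided",
    method = "Odds ratio with Wald CI and chi-square test",
    data.name = sprintf("2x2 table (%g, %g, %g, %g)", a, b, c, d)
  )
  attr(out$conf.int, "conf.level") <- level
  structure(out, class = "htest")
}

# Null distribution of the Mann-Whitney U statistic: number of ways to
# choose nx of the N pooled ranks with each possible rank sum (subset-sum
# dynamic programme), shifted to U = ranksum - nx(nx+1)/2.
mwu_null_counts <- function(nx, ny) {
  nn <- nx + ny
  max_sum <- sum((ny + 1):nn)
  # g[k+1, s+1] = subsets of size k of the ranks seen so far with sum s
  g <- matrix(0, nx + 1, max_sum + 1)
  g[1, 1] <- 1
  for (r in seq_len(nn)) {
    for (k in min(r, nx):1) {
      smax <- max_sum - r
      g[k + 1, (r + 1):(smax + r + 1)] <-
        g[k + 1, (r + 1):(smax + r + 1)] + g[k, 1:(smax + 1)]
    }
  }
  sums <- sum(1:nx):max_sum
  g[nx + 1, sums + 1]   # index u+1 corresponds to U = u in 0..nx*ny
}

#' Mann-Whitney U test
#'
#' Exact two-tailed p-value by enumeration of the null distribution of U
#' when `min(nx, ny) <= exact_limit` and the data contain no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest `min(nx, ny)` for which the exact
#'   distribution is enumerated.
#' @return An `htest` with the U statistic (for `x`) and two-tailed
#'   p-value.
#' @examples
#' mann_whitney_u(1:3, 4:6)$p.value   # 0.1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && min(nx, ny) <= exact_limit) {
    cnt <- mwu_null_counts(nx, ny)
    tot <- sum(cnt)
    lo <- min(u, nx * ny - u)
    p <- min(1, 2 * sum(cnt[seq_len(lo + 1)]) / tot)
    method <- "Mann-Whitney U test (exact)"
  } else {
    nn <- nx + ny
    mu <- nx * ny / 2
    tab <- table(r)
    tiecor <- sum(tab^3 - tab) / (nn * (nn - 1))
    sigma <- sqrt(nx * ny / 12 * ((nn + 1) - tiecor))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(
    statistic = c(U = u), p.value = min(1, p),
    alternative = "two.sided", method = method,
    data.name = sprintf("x (n=%d) vs y (n=%d)", nx, ny)
  ), class = "htest")
}

#' Fisher exact test for a 2x2 table
#'
#' Two-tailed p-value by summing all hypergeometric tables (with the
#' observed margins) whose point probability does not exceed that of the
#' observed table.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = outcomes.
#' @return An `htest` with the conditional hypergeometric p-value and the
#'   sample odds ratio.
#' @examples
#' fisher_exact_2x2(1, 1, 1, 1)$p.value   # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 + m2 == 0 || ((a + b == 0 || c + d == 0) && (a + c == 0 || b + d == 0)))
    stop("degenerate table: a margin is entirely zero")
  support <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  structure(list(
    statistic = c(a = a), p.value = p,
    estimate = c("sample odds ratio" = if (b * c > 0) (a * d) / (b * c) else NA_real_),
    alternative = "two.sided",
    method = "Fisher exact test (two-tailed, minlike)",
    data.name = sprintf("2x2 table (%d, %d, %d, %d)", a, b, c, d)
  ), class = "htest")
}

#' Spearman rank correlation
#'
#' Correlation of average ranks. The p-value uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom, or an
#' exact permutation distribution (all `n!` orderings) when
#' `exact = TRUE` and `n <= 8`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param exact Use the exact permutation null distribution?
#' @return An `htest` with `estimate = rho` and the two-tailed p-value.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p available only for n <= 8")
    perms <- permutations_all(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "Spearman rank correlation (t approximation)"
  }
  structure(list(
    statistic = c(S = sum((rx - ry)^2)), estimate = c(rho = rho),
    p.value = min(1, p), alternative = "two.sided", method = method,
    data.name = sprintf("x, y (n=%d)", n)
  ), class = "htest")
}

# All permutations of 1..n as a matrix (n! rows), recursively.
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation test for a group-by-time interaction
#'
#' Given one equal-length response series per animal and a group label
#' per animal, computes the interaction sum of squares of the two-way
#' (group x time) decomposition and compares it to its permutation null
#' obtained by reshuffling group labels across animals. Offered as a
#' distribution-free alternative to a repeated-measures two-way ANOVA
#' interaction test.
#'
#' @param series Numeric matrix, one row per animal, one column per time
#'   point.
#' @param groups Group label per animal (length `nrow(series)`).
#' @param n_perm Number of label permutations.
#' @param seed Optional integer; if given, the RNG is seeded locally.
#' @return An `htest` with the observed interaction SS and the
#'   permutation p-value `(1 + #{SS* >= SS}) / (1 + n_perm)`.
#' @export
permutation_interaction_test <- function(series, groups, n_perm = 999,
                                         seed = NULL) {
  series <- as.matrix(series)
  if (nrow(series) != length(groups))
    stop("one group label required per row of series")
  if (length(unique(groups)) < 2) stop("need at least two groups")
  if (n_perm < 99) warning("n_perm < 99 gives a very coarse p-value grid")
  if (!is.null(seed)) set.seed(seed)
  ss_int <- function(g) {
    grand <- mean(series)
    gm <- rowsum(series, g) / as.vector(table(g))   # group x time means
    row_eff <- rowMeans(gm) - grand
    col_eff <- colMeans(series) - grand
    # interaction deviation: cell mean - group effect - time effect + grand
    dev <- sweep(sweep(gm, 1, row_eff + grand), 2, col_eff)
    sum(as.vector(table(g)) * rowSums(dev^2))
  }
  obs <- ss_int(groups)
  perm <- replicate(n_perm, ss_int(sample(groups)))
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  structure(list(
    statistic = c("interaction SS" = obs), p.value = p,
    alternative = "greater",
    method = sprintf("Permutation interaction test (%d permutations)",
                     n_perm),
    data.name = sprintf("%d series x %d time points", nrow(series),
                        ncol(series))
  ), class = "htest")
}
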