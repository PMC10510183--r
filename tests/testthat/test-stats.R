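test_that("two-tailed binomial test matches brute-force enumeration and base R", {
  for (n in c(1, 5, 10, 12)) {
    for (k in 0:n) {
      for (p0 in c(0.3, 0.5, 0.7)) {
        ours <- binom_test_two_tailed(k, n, p0)$p.value
        expect_equal(ours, brute_binom_p(k, n, p0), tolerance = 1e-10,
                     info = sprintf("k=%d n=%d p0=%g", k, n, p0))
        expect_equal(ours, stats::binom.test(k, n, p0)$p.value,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("binomial test frozen examples and conventions", {
  # symmetric case: half the trials successful under p0 = 0.5
  expect_equal(binom_test_two_tailed(103, 206, 0.5)$p.value, 1)
  expect_equal(binom_test_two_tailed(0, 10, 0.5)$p.value, 2 / 1024)
  # enumerated: 90/206 vs 0.5 (the "third meal before a seizure" scale)
  expect_equal(binom_test_two_tailed(90, 206, 0.5)$p.value, 0.08128651,
               tolerance = 1e-6)
  # two-tailed >= one-tailed
  one_tail <- stats::pbinom(3, 12, 0.5)
  expect_gte(binom_test_two_tailed(3, 12, 0.5)$p.value, one_tail)
  # doubled convention differs but stays in [0, 1]
  pd <- binom_test_two_tailed(3, 12, 0.3, convention = "doubled")$p.value
  expect_gte(pd, 0); expect_lte(pd, 1)
  expect_error(binom_test_two_tailed(5, 4, 0.5))
  expect_error(binom_test_two_tailed(1, 4, 1))
})

test_that("Wilson interval has known endpoints and symmetry", {
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  ci <- wilson_ci(5, 10)
  expect_equal(unname(ci[1] + ci[2]), 1, tolerance = 1e-12) # symmetric about 0.5
  ci206 <- wilson_ci(103, 206)
  expect_equal(unname(ci206), c(0.4323493, 0.5676507), tolerance = 1e-6)
  expect_error(wilson_ci(1, 0))
})

test_that("odds ratio computes OR, Haldane correction, Wald CI and chi-square p", {
  o <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(unname(o$estimate), 1)
  expect_true(o$conf.int[1] < 1 && o$conf.int[2] > 1)
  expect_equal(unname(odds_ratio_2x2(5, 95, 20, 80)$estimate), 400 / 1900,
               tolerance = 1e-12)
  # zero cell: 0.5 added to every cell
  oc <- odds_ratio_2x2(0, 10, 10, 10)
  expect_equal(unname(oc$estimate), (0.5 * 10.5) / (10.5 * 10.5),
               tolerance = 1e-12)
  expect_true(oc$corrected)
  # Wald CI formula check against direct arithmetic
  o2 <- odds_ratio_2x2(12, 30, 25, 40)
  se <- sqrt(1 / 12 + 1 / 30 + 1 / 25 + 1 / 40)
  lor <- log((12 * 40) / (30 * 25))
  expect_equal(o2$conf.int, exp(lor + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(o2$statistic), lor / se, tolerance = 1e-12)
  # chi-square p agrees with base R without continuity correction
  base_p <- stats::chisq.test(matrix(c(12, 25, 30, 40), 2),
                              correct = FALSE)$p.value
  expect_equal(o2$p.value, base_p, tolerance = 1e-10)
  # no integer overflow at association-analysis scale
  big <- odds_ratio_2x2(25L, 244L, 1002L, 4179L)
  expect_false(is.na(big$p.value))
  expect_error(odds_ratio_2x2(0, 0, 5, 5))
})

test_that("Mann-Whitney exact p matches enumeration; approximation matches base R", {
  expect_equal(unname(mann_whitney_u(1:3, 4:6)$statistic), 0)
  expect_equal(mann_whitney_u(1:3, 4:6)$p.value, 0.1)
  set.seed(41)
  for (rep in 1:12) {
    nx <- sample(2:5, 1); ny <- sample(2:7, 1)
    v <- sample(1000, nx + ny)                       # distinct, no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mann_whitney_u(x, y)$p.value, brute_mwu_p(x, y),
                 tolerance = 1e-12)
    expect_equal(mann_whitney_u(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # identical samples sit at the centre of the null
  ident <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ident$statistic), 4.5)
  expect_gt(ident$p.value, 0.9)
  # normal approximation path (large/tied) tracks base R
  set.seed(42)
  x <- rpois(30, 8); y <- rpois(25, 10)
  expect_equal(mann_whitney_u(x, y)$p.value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-8)
  expect_error(mann_whitney_u(numeric(0), 1:3))
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p.value, 1)
  # enumerated value for the responder-rate comparison shape
  expect_equal(fisher_exact_2x2(5, 5, 0, 12)$p.value,
               brute_fisher_p(5, 5, 0, 12), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 0, 12)$p.value, 0.009569378,
               tolerance = 1e-8)
  # all tables with total n <= 12 against brute force and base R
  for (a in 0:3) for (b in 0:3) for (c in 0:3) for (d in 0:3) {
    if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) next
    p <- fisher_exact_2x2(a, b, c, d)$p.value
    expect_equal(p, brute_fisher_p(a, b, c, d), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-7)
  }
  # invariance to transposition
  expect_equal(fisher_exact_2x2(2, 7, 5, 1)$p.value,
               fisher_exact_2x2(2, 5, 7, 1)$p.value)
  expect_error(fisher_exact_2x2(0, 0, 0, 0))
})

test_that("Spearman rho and p behave across monotone, reversed and noisy input", {
  x <- c(1, 3, 5, 7, 11, 13)
  expect_equal(unname(spearman_rho(x, x^2)$estimate), 1)
  expect_equal(unname(spearman_rho(x, -x)$estimate), -1)
  set.seed(7)
  for (rep in 1:5) {
    xx <- rnorm(9); yy <- rnorm(9)
    ours <- spearman_rho(xx, yy)
    base <- suppressWarnings(stats::cor.test(xx, yy, method = "spearman"))
    expect_equal(unname(ours$estimate), unname(base$estimate),
                 tolerance = 1e-12)
  }
  # exact permutation p against independent full enumeration
  # (n = 5 -> 120 orderings enumerated in the test itself)
  xe <- c(1, 2, 3, 4, 5); ye <- c(2, 1, 3, 5, 4)
  pe <- spearman_rho(xe, ye, exact = TRUE)$p.value
  enum <- function(v) if (length(v) == 1) list(v) else
    unlist(lapply(seq_along(v), function(i)
      lapply(enum(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  rho_obs <- cor(rank(xe), rank(ye))
  rho_all <- vapply(enum(ye), function(p) cor(rank(xe), rank(p)),
                    numeric(1))
  expect_equal(pe, mean(abs(rho_all) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5))
  expect_error(spearman_rho(1:2, 1:2))
})

test_that("permutation interaction test calibrates and detects divergence", {
  set.seed(11)
  # identical series in every animal: no permutation can beat it
  flat <- matrix(rep(1:6, each = 8), nrow = 8, byrow = FALSE)
  g <- rep(c("A", "B"), each = 4)
  expect_equal(permutation_interaction_test(flat, g, 199)$p.value, 1)
  # strong group-by-time divergence: small p
  t <- 1:6
  diverge <- rbind(matrix(rep(t, 4), 4, byrow = TRUE) + rnorm(24, 0, 0.1),
                   matrix(rep(-t, 4), 4, byrow = TRUE) + rnorm(24, 0, 0.1))
  p <- permutation_interaction_test(diverge, g, 499)$p.value
  expect_lt(p, 0.05)
  # null calibration: p roughly uniform (coarse MC check on the mean)
  pn <- replicate(60, permutation_interaction_test(
    matrix(rnorm(48), 8), sample(g), 99)$p.value)
  expect_gt(mean(pn), 0.3); expect_lt(mean(pn), 0.7)
  expect_warning(permutation_interaction_test(flat, g, 50))
})
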