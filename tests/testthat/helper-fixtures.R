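# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

one_animal <- function(group = "HALF", rate = 5, cluster = 0,
                       id = "a1") {
  data.frame(animal_id = id, group = group, baseline_rate = rate,
             cluster_propensity = cluster, body_weight_g = 400,
             stringsAsFactors = FALSE)
}

# A hand-built meal grid for one animal: q.i.d. from t = 0, all
# delivered, medication given by `med` (recycled logical).
toy_meals <- function(n = 8, med = FALSE, phase = "TREATMENT",
                      id = "a1", gap = 6) {
  if (n == 0)
    return(data.frame(animal_id = character(), time_h = numeric(),
                      phase = character(), medicated = logical(),
                      delivered = logical(), dose_mg_per_kg = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(animal_id = id, time_h = (seq_len(n) - 1) * gap,
             phase = rep(phase, length.out = n),
             medicated = rep(med, length.out = n),
             delivered = TRUE,
             dose_mg_per_kg = ifelse(rep(med, length.out = n), 2.5, 0),
             stringsAsFactors = FALSE)
}

toy_seizures <- function(times, racine = 3, id = "a1") {
  data.frame(animal_id = id, time_h = times,
             racine = rep(racine, length.out = length(times)),
             stringsAsFactors = FALSE)
}

# Brute-force two-tailed binomial p by direct PMF computation (factorial
# form; independent of dbinom and of the package implementation).
brute_binom_p <- function(k, n, p0) {
  pmf <- vapply(0:n, function(i)
    exp(lgamma(n + 1) - lgamma(i + 1) - lgamma(n - i + 1) +
          i * log(p0) + (n - i) * log(1 - p0)), numeric(1))
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Brute-force exact Mann-Whitney two-tailed p by enumerating all
# placements of the x-sample among the pooled ranks.
brute_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  lo <- min(u_obs, nx * ny - u_obs)
  min(1, (sum(us <= lo) + sum(us >= nx * ny - lo)) / ncol(combos))
}

# Brute-force Fisher two-tailed p by enumerating every table with the
# observed margins and summing those no more probable than observed.
brute_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  pr <- vapply(support, function(x)
    choose(m1, x) * choose(m2, k - x) / choose(m1 + m2, k), numeric(1))
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
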