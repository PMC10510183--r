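#' Generate a synthetic cohort of epileptic animals
#'
#' Draws per-animal baseline seizure rates i.i.d. from a lognormal
#' distribution, reflecting the large inter-animal variability in
#' spontaneous seizure frequency typical of post-status-epilepticus
#' models. Animals are assigned to a fully adherent (`"FULL"`) or
#' partially adherent (`"HALF"`) group.
#'
#' The default rate distribution (median 5 stage-3+ seizures per week,
#' `sdlog = 0.6`) puts nearly all animals above the usual enrollment
#' criterion of at least one convulsive seizure per week while spanning an
#' order of magnitude across the cohort.
#'
#' @param n_full,n_half Number of animals in the fully / partially
#'   adherent groups (the canonical study used 10 and 12).
#' @param rate_meanlog,rate_sdlog Parameters of the lognormal baseline
#'   seizure rate (expected stage-3+ seizures per week).
#' @param cluster_propensity Probability that a simulated seizure spawns a
#'   cluster (extra seizures within the same inter-meal interval).
#' @param body_weight_g Body weight assigned to every animal (doses are
#'   expressed per kg so this is informational).
#' @param seed Optional integer; if given, the RNG is seeded locally.
#' @return A data frame with one row per animal: `animal_id`, `group`,
#'   `baseline_rate`, `cluster_propensity`, `body_weight_g`.
#' @examples
#' gen_animals(10, 12, seed = 1)
#' @export
gen_animals <- function(n_full, n_half, rate_meanlog = log(5),
                        rate_sdlog = 0.6, cluster_propensity = 0.25,
                        body_weight_g = 400, seed = NULL) {
  if (length(n_full) != 1 || length(n_half) != 1 ||
      n_full < 0 || n_half < 0 || n_full != round(n_full) ||
      n_half != round(n_half))
    stop("n_full and n_half must be non-negative integers")
  stopifnot(rate_sdlog >= 0, cluster_propensity >= 0, cluster_propensity <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_full + n_half
  if (n == 0)
    return(data.frame(animal_id = character(), group = character(),
                      baseline_rate = numeric(),
                      cluster_propensity = numeric(),
                      body_weight_g = numeric(),
                      stringsAsFactors = FALSE))
  group <- c(rep("FULL", n_full), rep("HALF", n_half))
  data.frame(
    animal_id = sprintf("%s%02d", ifelse(group == "FULL", "F", "H"),
                        c(seq_len(n_full), seq_len(n_half))[seq_len(n)]),
    group = group,
    baseline_rate = stats::rlnorm(n, rate_meanlog, rate_sdlog),
    cluster_propensity = cluster_propensity,
    body_weight_g = body_weight_g,
    stringsAsFactors = FALSE
  )
}
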