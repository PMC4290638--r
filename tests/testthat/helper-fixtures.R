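# Shared fixtures and independent oracles used across test files.

# Brute-force Mann-Whitney AUC: exhaustive positive-negative pair counting
# with half credit for ties.  Independent of the package's rank-based path.
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Small planted-signal cohort: balanced classes, strong shift on `subset`.
make_planted_cohort <- function(subset = c(3, 5, 18), delta = 1.2,
                                n_pos = 31, n_neg = 604, seed = 101) {
  cfg <- cohort_config("hc-conversion", n_positive = n_pos,
                       n_negative = n_neg, seed = seed)
  generate_cohort(plant_signal(cfg, subset, delta))
}

# Null cohort: no class separation anywhere (delta = 0 plant).
make_null_cohort <- function(n_pos = 100, n_neg = 100, seed = 202) {
  cfg <- cohort_config("hc-conversion", n_positive = n_pos,
                       n_negative = n_neg, seed = seed)
  generate_cohort(plant_signal(cfg, integer(0), 0))
}

# Simulate a small cohort directly from the logistic model with known
# coefficients over iid standard-normal features (generator for
# parameter-recovery oracles; independent of the cohort simulator).
simulate_logistic <- function(beta0, beta, n, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n, length(beta))
    t <- beta0 + drop(X %*% beta)
    y <- rbinom(n, 1, plogis(t))
    list(X = X, y = y)
  })
}
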