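# Shared fixtures built in code.

# Brute-force AUC: all (positive, negative) pairs, half credit for ties.
brute_force_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small cohort used across tests (frozen seed, fast).
tiny_cohort <- function(n = 99, seed = 11) {
  generate_cohort(cohort_config(n = n, seed = seed))
}

# A numerically easy logistic regression problem.
sim_logistic <- function(n, beta0, beta1, seed) {
  set.seed(seed)
  x <- rnorm(n)
  p <- plogis(beta0 + beta1 * x)
  y <- rbinom(n, 1, p)
  list(x = x, y = y, p = p)
}
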