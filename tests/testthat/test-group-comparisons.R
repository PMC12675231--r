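test_that("Kruskal-Wallis matches the brute-force rank formula", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  # hand oracle: H = 12/(N(N+1)) sum(R_i^2/n_i) - 3(N+1), no ties
  res <- kruskal_wallis(v, g)
  expect_equal(res$H, 12 / (9 * 10) * ((6^2 + 15^2 + 24^2) / 3) - 3 * 10)
  expect_equal(res$df, 2)
  # fully tied sample is degenerate with H = 0
  res0 <- kruskal_wallis(rep(5, 9), g)
  expect_equal(res0$H, 0)
  expect_true(res0$degenerate)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 non-empty")
})

test_that("Kruskal-Wallis holds its nominal type-I error rate", {
  rejections <- 0
  for (s in 1:1000) {
    set.seed(s)
    v <- rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    if (kruskal_wallis(v, g)$p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 1000, 0.03)
  expect_lte(rejections / 1000, 0.07)
})

test_that("Dunn z^2 equals H for two groups without ties", {
  set.seed(4)
  v <- sample(1:40, 20)
  g <- rep(c("a", "b"), each = 10)
  d <- dunn_posthoc(v, g)
  expect_equal(nrow(d), 1)
  expect_equal(d$z^2, kruskal_wallis(v, g)$H, tolerance = 1e-12)
})

test_that("Dunn handles ties with the tie-corrected standard error", {
  v <- c(1, 2, 2, 3, 3, 3, 4, 5, 5, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- dunn_posthoc(v, g, adjust = "bonferroni")
  expect_equal(nrow(d), 3)  # k(k-1)/2 pairs
  # hand oracle for the a-b pair
  N <- length(v)
  r <- rank(v)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / 4 + 1 / 4))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab,
               tolerance = 1e-12)
  expect_true(all(d$p_adjusted >= d$p))
  expect_true(all(d$p_adjusted <= 1))
})

test_that("four groups give six Dunn pairs", {
  ch <- tiny_cohort(n = 150, seed = 9)
  d <- dunn_posthoc(ch$oxytocin, ch$phenotype)
  expect_equal(nrow(d), 6)
})

test_that("multiplicity adjustments match their step definitions", {
  expect_equal(adjust_pvalues(0.03, "bh"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  # brute-force BH step-up
  p <- c(0.01, 0.02, 0.04, 0.80)
  expect_equal(adjust_pvalues(p, "bh"), c(0.04, 0.04, 0.04 * 4 / 3, 0.80))
  # BH never exceeds Bonferroni for the smallest p
  set.seed(2)
  for (i in 1:20) {
    ps <- runif(6)
    expect_lte(min(adjust_pvalues(ps, "bh")),
               min(adjust_pvalues(ps, "bonferroni")))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman matrix is symmetric, rank-invariant and flagged", {
  set.seed(3)
  df <- data.frame(x = rnorm(30))
  df$neg <- -df$x
  df$mono <- exp(df$x)
  m <- spearman_matrix(df, c("x", "neg", "mono"))
  expect_equal(unname(diag(m$rho)), c(1, 1, 1))
  expect_equal(m$rho["x", "neg"], -1)
  expect_equal(m$rho["x", "mono"], 1)
  expect_identical(m$rho, t(m$rho))
  df$flat <- 1
  m2 <- spearman_matrix(df, c("x", "flat"))
  expect_true("flat" %in% attr(m2, "flagged"))
  expect_true(is.na(m2$rho["x", "flat"]))
})

test_that("prevalence counts use >= and report percentages", {
  df <- data.frame(s = c(1, 4, 5))
  out <- prevalence_table(df, c(s = 4.0))
  expect_equal(out$count, 2)
  expect_equal(out$percent, 100 * 2 / 3)
  empty <- prevalence_table(df[0, , drop = FALSE], c(s = 4.0))
  expect_equal(empty$count, 0)
  expect_error(prevalence_table(df, c(missing_scale = 1)), "unknown")
})

test_that("Cohen's d uses the pooled SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(8)
  a <- rnorm(400, 1, 1); b <- rnorm(400, 0, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.15)
  # hand oracle on toy vectors
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6)
  sp <- sqrt((3 * var(x) + 2 * var(y)) / 5)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "pooled SD")
})

test_that("compare_groups reports BH q-values and the family size", {
  ch <- tiny_cohort(n = 120, seed = 13)
  ch <- add_metabolic_indices(ch)
  res <- compare_groups(ch, c("oxytocin", "leptin", "edeq_global"))
  expect_equal(res$tests$family_size[1], 3)
  expect_true(all(res$tests$q >= res$tests$p, na.rm = TRUE))
  expect_named(res$posthoc, c("oxytocin", "leptin", "edeq_global"))
})
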