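test_that("AUC equals brute-force pair concordance, ties included", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    p <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(p, y), brute_force_auc(p, y), tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  set.seed(52)
  p <- runif(40); y <- rbinom(40, 1, 0.5)
  expect_equal(auc(p, y), auc(qlogis(p), y))
  expect_error(auc(runif(5), rep(1, 5)), "both")
})

test_that("Brier score matches its closed forms", {
  expect_equal(brier(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0)
  y <- rep(c(1, 0), c(30, 70))
  p <- 0.3
  expect_equal(brier(rep(p, 100), y), p^2 * 0.7 + (1 - p)^2 * 0.3)
  pi0 <- 0.3
  expect_equal(brier(rep(pi0, 100), y), pi0 * (1 - pi0))
  expect_error(brier(c(-0.1, 0.5), c(0, 1)), "\\[0, 1\\]")
})

test_that("Youden point maximizes J with specificity-favoring ties", {
  yj <- youden_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), B = 200,
                     seed = 1)
  expect_equal(yj$J, 1)
  expect_equal(yj$sens, 1)
  expect_equal(yj$spec, 1)
  # 10-point toy vector against an exhaustive scan
  set.seed(53)
  p <- round(runif(10), 2)
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0)
  yj2 <- youden_point(p, y, B = 200, seed = 1)
  th <- sort(unique(p))
  Js <- sapply(th, function(t) {
    mean(p[y == 1] >= t) + mean(p[y == 0] < t) - 1
  })
  expect_equal(yj2$J, max(Js), tolerance = 1e-12)
  expect_true(yj2$p_star %in% th[Js == max(Js)])
  # under independence J stays near zero
  set.seed(54)
  p3 <- runif(4000); y3 <- rbinom(4000, 1, 0.5)
  expect_lt(youden_point(p3, y3, B = 100, seed = 1)$J, 0.12)
})

test_that("paired bootstrap Delta AUC behaves at the null and rejects signal", {
  p <- c(0.2, 0.3, 0.6, 0.8, 0.4, 0.7)
  y <- c(0, 0, 1, 1, 0, 1)
  self <- paired_delta_auc(p, p, y, B = 500, seed = 2)
  expect_equal(self$delta, 0)
  expect_equal(self$p, 1)  # exactly 1 after capping the corrected p
  expect_true(self$ci[1] <= 0 && self$ci[2] >= 0)
  expect_error(paired_delta_auc(p, p, y, B = 0), "B must be")
  expect_error(paired_delta_auc(p[1:5], p, y), "same participants")
  # informative vs pure-noise model: CI excludes zero in most seeds
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    n <- 150
    x <- rnorm(n)
    y2 <- rbinom(n, 1, plogis(2.5 * x))
    good <- plogis(2.5 * x)
    noise <- runif(n)
    d <- paired_delta_auc(noise, good, y2, B = 300, seed = s)
    if (d$ci[1] > 0) hits <- hits + 1
  }
  expect_gte(hits, 36)  # >= 90%
})

test_that("recalibration recovers known miscalibration patterns", {
  set.seed(55)
  n <- 2000
  p_true <- plogis(rnorm(n, 0, 1.2))
  y <- rbinom(n, 1, p_true)
  cal <- calibration(p_true, y)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_gt(cal$intercept, -0.15); expect_lt(cal$intercept, 0.15)
  # systematically doubled odds: slope ~ 1, offset intercept ~ -log 2
  p_double <- plogis(qlogis(p_true) + log(2))
  cal2 <- calibration(p_double, y)
  expect_equal(cal2$slope, 1, tolerance = 0.1)
  expect_equal(cal2$intercept, -log(2), tolerance = 0.12)
  # uninformative predictions: slope ~ 0
  cal3 <- calibration(runif(n), rbinom(n, 1, 0.5))
  expect_lt(abs(cal3$slope), 0.12)
  # degenerate constant predictions flagged
  expect_true(calibration(rep(0.4, 50), rbinom(50, 1, 0.4))$degenerate)
  expect_equal(sum(cal$reliability$n), n)
})

test_that("threshold inversion finds interpolated crossings", {
  # synthetic monotone curve with a known analytic crossing
  grid <- seq(10, 200, length.out = 96)
  fit <- plogis(5 - 0.05 * grid)  # crosses p* where 5 - 0.05 x = logit(p*)
  fake <- structure(list(
    curve = data.frame(x = grid, fit = fit, lower = fit, upper = fit),
    boot = matrix(rep(fit, 50), nrow = 50, byrow = TRUE)),
    class = "phenospline_curve")
  p_star <- 0.69
  m <- map_threshold_to_biomarker(fake, p_star)
  x_true <- (5 - qlogis(p_star)) / 0.05
  expect_true(m$found)
  expect_equal(m$cutoff, x_true, tolerance = m$grid_step / 10)
  expect_equal(nrow(m$crossings), 1)
  expect_equal(m$crossings$direction, "down")
  # identical bootstrap replicates give a zero-width interval
  expect_equal(m$ci[1], m$ci[2], tolerance = 1e-12)
  # a curve entirely below the threshold yields an empty flagged mapping
  low <- fake
  low$curve$fit <- rep(0.2, 96)
  low$boot <- matrix(0.2, nrow = 50, ncol = 96)
  m2 <- map_threshold_to_biomarker(low, 0.69)
  expect_false(m2$found)
  expect_true(is.na(m2$cutoff))
  expect_error(map_threshold_to_biomarker(fake, 1.2), "p_star")
})

test_that("roc_result agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(56)
  p <- runif(80); y <- rbinom(80, 1, plogis(3 * (p - 0.5)))
  r <- roc_result(p, y, B = 200, seed = 3)
  independent <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(r$auc, independent, tolerance = 1e-10)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
})
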