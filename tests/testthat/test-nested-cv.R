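test_that("fold plans are stratified partitions, reproducible by seed", {
  set.seed(41)
  y <- rbinom(99, 1, 0.64)
  while (abs(mean(y) - 0.64) > 0.02) y <- rbinom(99, 1, 0.64)
  p1 <- make_fold_plan(y, seed = 3)
  p2 <- make_fold_plan(y, seed = 3)
  expect_identical(p1$outer, p2$outer)
  sizes <- sort(as.integer(table(p1$outer)))
  expect_equal(sizes, c(19, 20, 20, 20, 20))
  # stratification: per-fold event fraction close to overall
  for (f in 1:5) {
    expect_lt(abs(mean(y[p1$outer == f]) - mean(y)), 0.06 + 1e-9)
  }
  # inner folds partition the outer-train set and avoid the test set
  for (f in 1:5) {
    inner <- p1$inner[[f]]
    expect_true(all(is.na(inner[p1$outer == f])))
    expect_true(all(!is.na(inner[p1$outer != f])))
    expect_setequal(unique(inner[!is.na(inner)]), 1:5)
  }
  expect_error(make_fold_plan(c(rep(0, 95), rep(1, 4)), outer_k = 5),
               "class")
})

test_that("elastic net honors its optimality contracts", {
  set.seed(42)
  n <- 400
  X <- scale(matrix(rnorm(n * 3), ncol = 3))
  colnames(X) <- c("a", "b", "c")
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  # lambda -> 0 recovers the unpenalized MLE
  path <- exp(seq(log(0.5), log(1e-8), length.out = 60))
  fit <- enet_logistic(X, y, alpha = 0.5, lambda = path)
  cf <- as.numeric(coef(fit, s = 1e-8))
  mle <- coef(glm(y ~ X, family = binomial()))
  expect_lt(max(abs(cf - mle)), 1e-4)
  # large lambda with alpha = 1 gives full shrinkage
  fit2 <- enet_logistic(X, y, alpha = 1, lambda = c(10, 5))
  cf2 <- as.numeric(coef(fit2, s = 10))
  expect_equal(cf2[-1], rep(0, 3))
  expect_equal(cf2[1], qlogis(mean(y)), tolerance = 1e-6)
  # ridge symmetry for duplicated predictors
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  colnames(Xd) <- c("d1", "d2", "e")
  fit3 <- enet_logistic(Xd, y, alpha = 0, lambda = c(0.5, 0.1))
  cf3 <- as.numeric(coef(fit3, s = 0.1))
  expect_lt(abs(cf3[2] - cf3[3]), 1e-6)
  # KKT residuals near zero at an on-path solution
  path_k <- sort(unique(c(path, 0.05)), decreasing = TRUE)
  fit_k <- enet_logistic(X, y, alpha = 0.5, lambda = path_k)
  cf4 <- as.numeric(coef(fit_k, s = 0.05))
  expect_lt(kkt_residuals(X, y, cf4[1], cf4[-1], 0.5, 0.05), 1e-6)
})

test_that("out-of-fold predictions cover everyone exactly once", {
  ch <- tiny_cohort(n = 99, seed = 21)
  ch <- add_metabolic_indices(ch)
  y <- as.integer(ch$edeq_global >= 2.5)
  plan <- make_fold_plan(y, seed = 2)
  oof <- collect_oof(ch, y, list(model_spec("oxytocin_only"),
                                 model_spec("combined")), plan)
  pr <- oof$predictions
  expect_equal(nrow(pr), 99)
  expect_true(all(is.finite(pr$p_oxytocin_only)))
  expect_true(all(is.finite(pr$p_combined)))
  expect_true(all(pr$p_combined > 0 & pr$p_combined < 1))
  # determinism: same cohort + plan -> bit-identical probabilities
  oof2 <- collect_oof(ch, y, list(model_spec("combined")), plan)
  expect_identical(pr$p_combined, oof2$predictions$p_combined)
})

test_that("corrupting outer-test rows never changes fold parameters", {
  ch <- tiny_cohort(n = 99, seed = 22)
  ch <- add_metabolic_indices(ch)
  y <- as.integer(ch$edeq_global >= 2.5)
  plan <- make_fold_plan(y, seed = 7)
  spec <- model_spec("combined", n_lambda = 20)
  f <- 1
  tr <- which(plan$outer != f)
  fit_clean <- fit_fold(ch[tr, ], y[tr], spec,
                        inner_fold = plan$inner[[f]][tr])
  corrupted <- ch
  te <- which(plan$outer == f)
  corrupted[te, c("oxytocin", "leptin", "bmi", "wc")] <- 1e6
  fit_corr <- fit_fold(corrupted[tr, ], y[tr], spec,
                       inner_fold = plan$inner[[f]][tr])
  expect_identical(fit_clean$preprocessor, fit_corr$preprocessor)
  expect_identical(fit_clean$beta, fit_corr$beta)
  expect_identical(fit_clean$lambda, fit_corr$lambda)
})

test_that("a separable synthetic signal yields near-perfect OOF AUC", {
  set.seed(43)
  ch <- tiny_cohort(n = 99, seed = 23)
  # outcome driven hard by the biomarker itself
  y <- as.integer(ch$oxytocin < median(ch$oxytocin))
  plan <- make_fold_plan(y, seed = 4)
  oof <- collect_oof(ch, y, list(model_spec("oxytocin_only")), plan)
  expect_gt(auc(oof$predictions$p_oxytocin_only, y), 0.95)
})

test_that("the EDE-Q component can be excluded from the combined model", {
  ch <- tiny_cohort(n = 99, seed = 24)
  ch <- add_metabolic_indices(ch)
  y <- as.integer(ch$edeq_global >= 2.5)
  plan <- make_fold_plan(y, seed = 5)
  spec <- model_spec("combined", include_edeq_component = FALSE,
                     n_lambda = 20)
  tr <- which(plan$outer != 1)
  ff <- fit_fold(ch[tr, ], y[tr], spec,
                 inner_fold = plan$inner[[1]][tr])
  expect_null(ff$preprocessor$pca)
  expect_false("edeq_pc1" %in% names(ff$preprocessor$center))
})
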