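test_that("noise-free linear data give zero SEs and R^2 = 1", {
  df <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
  # summary.lm warns about the essentially perfect fit; that is the point
  fit <- suppressWarnings(fit_ols_hc3(df, "y", "x"))
  expect_equal(fit$r_squared, 1)
  expect_lt(max(fit$coefficients$se_hc3), 1e-8)
  expect_equal(fit$coefficients$B[2], 3, tolerance = 1e-10)
})

test_that("HC3 SEs equal the hand-computed sandwich on a toy dataset", {
  df <- data.frame(x = c(0, 1, 2, 3, 4, 5),
                   y = c(0.1, 1.3, 1.8, 3.4, 3.6, 5.5))
  fit <- fit_ols_hc3(df, "y", "x")
  X <- cbind(1, df$x)
  bread <- solve(crossprod(X))
  b <- bread %*% crossprod(X, df$y)
  e <- df$y - X %*% b
  h <- diag(X %*% bread %*% t(X))
  meat <- t(X) %*% diag(as.numeric(e^2) / (1 - h)^2) %*% X
  se_hand <- sqrt(diag(bread %*% meat %*% bread))
  expect_equal(fit$coefficients$se_hc3, se_hand, tolerance = 1e-10)
})

test_that("HC3 approaches the classical SE under homoskedasticity", {
  set.seed(21)
  n <- 5000
  df <- data.frame(x = rnorm(n))
  df$y <- 1 + 0.5 * df$x + rnorm(n)
  fit <- fit_ols_hc3(df, "y", "x")
  ratio <- fit$coefficients$se_hc3 / fit$coefficients$se_classical
  expect_true(all(ratio > 0.95 & ratio < 1.05))
})

test_that("rank-deficient designs fail with the collinear column named", {
  df <- data.frame(x = 1:10, y = rnorm(10))
  df$x2 <- 2 * df$x
  expect_error(fit_ols_hc3(df, "y", c("x", "x2")), "x2")
})

test_that("backward elimination keeps signal and drops noise", {
  set.seed(5)
  n <- 150
  df <- data.frame(x = rnorm(n))
  df$y <- 2 * df$x + rnorm(n)
  res <- backward_eliminate(df, "y", "x")
  expect_equal(res$final_predictors, "x")
  expect_equal(nrow(res$trace), 0)

  dropped <- 0
  for (s in 1:200) {
    set.seed(s)
    d <- data.frame(x = rnorm(100), z = rnorm(100))
    d$y <- 2 * d$x + rnorm(100)
    r <- backward_eliminate(d, "y", c("x", "z"))
    if (!"z" %in% r$final_predictors) dropped <- dropped + 1
  }
  expect_gte(dropped, 170)  # >= 85% of simulations

  # all-noise candidates can collapse to the intercept-only model
  set.seed(6)
  d <- data.frame(a = rnorm(60), b = rnorm(60), y = rnorm(60))
  r <- backward_eliminate(d, "y", c("a", "b"))
  expect_true(length(r$final_predictors) <= 2)
  expect_true(all(r$trace$p_at_drop >= 0.10))
})

test_that("VIF matches its closed form and flags perfect collinearity", {
  set.seed(9)
  # exactly orthogonal centered columns
  d <- data.frame(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(unname(vif(d)), c(1, 1))
  # exact correlation 0.9 construction: VIF = 1/(1 - 0.81)
  x1 <- c(1, -1, 1, -1); e <- c(1, 1, -1, -1)
  d2 <- data.frame(x1 = x1, x2 = 0.9 * x1 + sqrt(1 - 0.81) * e)
  expect_equal(unname(vif(d2)), rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
  d3 <- data.frame(u = 1:8, v = 2 * (1:8))
  expect_true(all(is.infinite(suppressWarnings(vif(d3)))))
})

test_that("VIF agrees with an independent implementation", {
  skip_if_not_installed("car")
  set.seed(10)
  d <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  d$y <- d$a + d$b + rnorm(50)
  mine <- vif(d[, c("a", "b", "c")])
  theirs <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(unname(mine), unname(theirs), tolerance = 1e-10)
})

test_that("PCA replacement is sign-oriented and captures shared variance", {
  set.seed(11)
  d <- data.frame(a = rnorm(80))
  d$b <- 2 * d$a + 5
  p <- pca_scores(d, c("a", "b"), k = 1)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  # component correlates non-negatively with the input mean
  expect_gte(cor(p$scores[, 1], d$a), 0)
  # flipping all inputs flips raw scores; orientation restores the sign
  d2 <- data.frame(a = -d$a, b = -d$b)
  p2 <- pca_scores(d2, c("a", "b"), k = 1)
  expect_gte(cor(p2$scores[, 1], d2$a), 0)
  expect_error(pca_scores(d, c("a", "b"), k = 3), "k exceeds")
  # independent variables spread variance roughly evenly
  set.seed(12)
  big <- as.data.frame(matrix(rnorm(4000 * 4), ncol = 4))
  pb <- pca_scores(big, names(big), k = 4)
  expect_true(all(abs(pb$explained - 0.25) < 0.05))
  expect_true(all(diff(pb$explained) <= 1e-12))
})

test_that("pca_project reproduces training scores and uses stored constants", {
  set.seed(13)
  d <- as.data.frame(matrix(rnorm(40 * 3), ncol = 3))
  p <- pca_scores(d, names(d), k = 2)
  expect_equal(unname(pca_project(p, d)), unname(p$scores),
               tolerance = 1e-10)
})

test_that("standardized betas obey their identities", {
  set.seed(14)
  n <- 200
  d <- data.frame(x = rnorm(n, sd = 1))
  d$y <- 2 * d$x + rnorm(n, sd = sqrt(max(0, 4 - 4 * var(d$x))))
  # beta = B * SD(x)/SD(y)
  fit <- fit_ols_hc3(d, "y", "x")
  expect_equal(unname(standardized_betas(fit)),
               fit$coefficients$B[2] * sd(d$x) / sd(d$y))
  # simple regression: beta equals Pearson r
  expect_equal(unname(standardized_betas(fit)), cor(d$x, d$y),
               tolerance = 1e-12)
  # multivariate case matches a brute-force z-scored refit
  d$z <- rnorm(n)
  d$y2 <- d$x - 0.5 * d$z + rnorm(n)
  fit2 <- fit_ols_hc3(d, "y2", c("x", "z"))
  zd <- as.data.frame(scale(d[, c("y2", "x", "z")]))
  refit <- lm(y2 ~ x + z, data = zd)
  expect_equal(unname(standardized_betas(fit2)),
               unname(coef(refit)[c("x", "z")]), tolerance = 1e-10)
})

test_that("elimination order does not depend on candidate ordering", {
  set.seed(15)
  d <- data.frame(a = rnorm(120), b = rnorm(120), c = rnorm(120))
  d$y <- d$a + 0.5 * d$b + rnorm(120)
  r1 <- backward_eliminate(d, "y", c("a", "b", "c"))
  r2 <- backward_eliminate(d, "y", c("c", "b", "a"))
  expect_setequal(r1$final_predictors, r2$final_predictors)
  expect_equal(r1$trace$dropped, r2$trace$dropped)
})
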