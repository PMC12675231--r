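# OLS with HC3 robust inference, backward elimination, collinearity
# diagnostics, standardized coefficients, and PCA replacement of
# correlated subscales.

#' OLS with HC3 robust standard errors
#'
#' Fits ordinary least squares and reports both classical and HC3
#' heteroskedasticity-consistent standard errors
#' (`(X'X)^-1 X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^-1`, via
#' [sandwich::vcovHC()]). Inference uses the t reference with n - p df on
#' the HC3 SEs. Standardized betas and per-predictor VIFs are attached.
#'
#' @param data Data.frame holding outcome and predictors.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @param conf_level Confidence level for the CIs (default 0.95).
#' @return Object of class `phenospline_ols`: `coefficients` table
#'   (B, classical SE, HC3 SE, CI bounds, standardized beta, p, VIF),
#'   `r_squared`, `adj_r_squared`, `n`, `outcome`, plus the underlying
#'   `lm` fit.
#' @export
fit_ols_hc3 <- function(data, outcome, predictors, conf_level = 0.95) {
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(predictors) == 0) {
    fm <- stats::as.formula(paste(outcome, "~ 1"))
  } else {
    fm <- stats::as.formula(paste(outcome, "~",
                                  paste(predictors, collapse = " + ")))
  }
  data <- data[stats::complete.cases(data[, c(outcome, predictors),
                                         drop = FALSE]), , drop = FALSE]
  n <- nrow(data)
  p <- length(predictors) + 1L
  if (n <= p) stop("need n > number of coefficients", call. = FALSE)
  fit <- stats::lm(fm, data = data)
  X <- stats::model.matrix(fit)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  b <- stats::coef(fit)
  vc_classical <- stats::vcov(fit)
  vc_hc3 <- sandwich::vcovHC(fit, type = "HC3")
  se_c <- sqrt(diag(vc_classical))
  se_r <- sqrt(diag(vc_hc3))
  df <- n - p
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  tval <- b / se_r
  pval <- 2 * stats::pt(-abs(tval), df)
  sdy <- stats::sd(data[[outcome]])
  beta_std <- vapply(names(b), function(nm) {
    if (nm == "(Intercept)") return(NA_real_)
    b[[nm]] * stats::sd(X[, nm]) / sdy
  }, numeric(1))
  vifs <- if (length(predictors) >= 2) {
    v <- vif(data[, predictors, drop = FALSE])
    c(`(Intercept)` = NA_real_, v[names(b)[-1]])
  } else {
    stats::setNames(rep(NA_real_, length(b)), names(b))
  }
  coefs <- data.frame(
    term = names(b), B = unname(b),
    se_classical = unname(se_c), se_hc3 = unname(se_r),
    ci_lower = unname(b - tcrit * se_r), ci_upper = unname(b + tcrit * se_r),
    beta_std = unname(beta_std), p = unname(pval), vif = unname(vifs),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  sm <- summary(fit)
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared, n = n, df = df,
                 outcome = outcome, predictors = predictors, lm_fit = fit),
            class = "phenospline_ols")
}

#' @export
print.phenospline_ols <- function(x, ...) {
  cat(sprintf("OLS (HC3 robust SE): %s ~ %s\n", x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  cat(sprintf("n = %d, R^2 = %.3f, adj R^2 = %.3f\n", x$n, x$r_squared,
              x$adj_r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Backward elimination on HC3 p-values
#'
#' Repeatedly drops the predictor with the largest HC3-based p-value at or
#' above `threshold` and refits, until every remaining predictor has
#' p < threshold (a predictor at exactly the threshold is dropped; the
#' retained set satisfies the strict inequality). The intercept is never
#' dropped. May terminate at the intercept-only model.
#'
#' @param data,outcome Passed to [fit_ols_hc3()].
#' @param candidates Initial predictor set (non-empty).
#' @param threshold Retention threshold (default 0.10).
#' @return List with `fit` (final `phenospline_ols`) and `trace`
#'   (data.frame of dropped predictors with the p-value at the drop).
#' @export
backward_eliminate <- function(data, outcome, candidates, threshold = 0.10) {
  if (length(candidates) == 0) stop("candidate set must be non-empty",
                                    call. = FALSE)
  current <- candidates
  trace <- data.frame(dropped = character(0), p_at_drop = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    fit <- fit_ols_hc3(data, outcome, current)
    ct <- fit$coefficients
    ct <- ct[ct$term != "(Intercept)", , drop = FALSE]
    if (nrow(ct) == 0 || max(ct$p) < threshold) break
    worst <- ct$term[which.max(ct$p)]
    trace <- rbind(trace, data.frame(dropped = worst,
                                     p_at_drop = max(ct$p),
                                     stringsAsFactors = FALSE))
    current <- setdiff(current, worst)
    if (length(current) == 0) {
      fit <- fit_ols_hc3(data, outcome, character(0))
      break
    }
  }
  list(fit = fit, trace = trace, final_predictors = current)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` is from regressing predictor j
#' on the remaining predictors. Perfectly collinear columns are reported
#' as `Inf`.
#'
#' @param design Data.frame or matrix of >= 2 predictors.
#' @return Named numeric vector of VIFs (each >= 1).
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) stop("VIF needs >= 2 predictors", call. = FALSE)
  vapply(names(design), function(j) {
    r2 <- summary(stats::lm(design[[j]] ~ .,
                            data = design[, setdiff(names(design), j),
                                          drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' PCA scores for correlated subscales
#'
#' Principal components of internally standardized variables (centered,
#' unit SD), with each component's sign oriented so that it correlates
#' non-negatively with the mean of its standardized inputs — replacing a
#' block of collinear questionnaire subscales with orthogonal scores.
#'
#' @param data Data.frame.
#' @param variables Columns to decompose.
#' @param k Number of components to keep (<= length(variables)).
#' @return List of class `phenospline_pca`: `loadings` (p x k),
#'   `explained` (variance ratios, nonincreasing), `scores` (n x k),
#'   `center`, `scale`, `flipped` (which components were sign-flipped).
#' @export
pca_scores <- function(data, variables, k = 1) {
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (k > length(variables)) stop("k exceeds the number of variables",
                                  call. = FALSE)
  X <- as.matrix(data[, variables, drop = FALSE])
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  Z <- scale(X, center = pc$center, scale = pc$scale)
  m <- rowMeans(Z)
  flipped <- logical(k)
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    cj <- stats::cov(scores[, j], m)
    if (is.finite(cj) && cj < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
      flipped[j] <- TRUE
    }
  }
  structure(list(loadings = loadings, explained = explained[seq_len(k)],
                 explained_all = explained, scores = scores,
                 center = pc$center, scale = pc$scale, flipped = flipped,
                 variables = variables),
            class = "phenospline_pca")
}

#' Project new data onto fitted PCA components
#'
#' @param pca A `phenospline_pca` object.
#' @param newdata Data.frame containing the PCA's input variables.
#' @return Matrix of component scores using the stored center/scale and
#'   loadings only.
#' @export
pca_project <- function(pca, newdata) {
  X <- as.matrix(newdata[, pca$variables, drop = FALSE])
  Z <- scale(X, center = pca$center, scale = pca$scale)
  Z %*% pca$loadings
}

#' Standardized regression coefficients
#'
#' `beta_j = B_j * SD(x_j) / SD(y)` for a fitted [fit_ols_hc3()] model.
#'
#' @param fit A `phenospline_ols` object.
#' @return Named vector of standardized betas (intercept excluded).
#' @export
standardized_betas <- function(fit) {
  ct <- fit$coefficients
  ct <- ct[ct$term != "(Intercept)", ]
  stats::setNames(ct$beta_std, ct$term)
}

#' Residual diagnostics for an OLS fit
#'
#' Shapiro-Wilk on residuals plus a residual-vs-fitted scatter (returned
#' as a ggplot, not auto-printed). No remedial action is taken.
#'
#' @param fit A `phenospline_ols` object.
#' @return List with `shapiro_p`, `plot`.
#' @export
residual_diagnostics <- function(fit) {
  res <- stats::residuals(fit$lm_fit)
  fitted <- stats::fitted(fit$lm_fit)
  gate <- normality_gate(res)
  df <- data.frame(fitted = fitted, residual = res)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = fitted, y = residual)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Fitted values", y = "Residuals")
  list(shapiro_p = gate$p, plot = p)
}
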