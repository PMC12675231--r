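# Leakage-free nested cross-validation producing out-of-fold predictions
# for (A) an oxytocin-only RCS logistic model and (B) a combined
# elastic-net model. All preprocessing (imputation, scaling, spline knot
# placement, PCA of the EDE-Q subscales) is learned on training data only
# and applied to held-out data through stored constants.

#' Build a stratified nested fold plan
#'
#' Outer k-fold assignment stratified by the binary outcome (per-fold
#' event counts differ by at most 1 from proportionality), plus an inner
#' k-fold assignment within each outer-training set, also stratified.
#' Inner folds never touch the outer test set. Deterministic given `seed`.
#'
#' @param outcomes Binary outcome vector (0/1).
#' @param outer_k,inner_k Fold counts (default 5 x 5).
#' @param seed Integer seed.
#' @return Object of class `phenospline_foldplan`: `outer` (fold id per
#'   participant), `inner` (list over outer folds; fold id per participant
#'   with NA at outer-test positions), `outer_k`, `inner_k`, `seed`.
#' @export
make_fold_plan <- function(outcomes, outer_k = 5, inner_k = 5, seed = 1) {
  y <- as.integer(outcomes)
  n <- length(y)
  if (min(table(y)) < outer_k) {
    stop("each outcome class needs at least `outer_k` members", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  outer <- .stratified_folds(y, outer_k)
  inner <- lapply(seq_len(outer_k), function(f) {
    train_idx <- which(outer != f)
    inner_f <- rep(NA_integer_, n)
    if (min(table(y[train_idx])) < inner_k) {
      stop("outer-train split leaves a class smaller than `inner_k`",
           call. = FALSE)
    }
    inner_f[train_idx] <- .stratified_folds(y[train_idx], inner_k)
    inner_f
  })
  structure(list(outer = outer, inner = inner, outer_k = outer_k,
                 inner_k = inner_k, seed = seed, n = n),
            class = "phenospline_foldplan")
}

# Stratified fold labels: within each class the base count per fold is
# floor(n_c / k); remainders go to the folds with the smallest running
# totals so overall fold sizes also differ by <= 1 where possible.
.stratified_folds <- function(y, k) {
  n <- length(y)
  fold <- integer(n)
  totals <- integer(k)
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    nc <- length(idx)
    base <- nc %/% k
    extra <- nc %% k
    counts <- rep(base, k)
    if (extra > 0) {
      recipients <- order(totals, seq_len(k))[seq_len(extra)]
      counts[recipients] <- counts[recipients] + 1L
    }
    fold[idx] <- rep.int(seq_len(k), counts)
    totals <- totals + counts
  }
  fold
}

#' Model specification for nested cross-validation
#'
#' @param id `"oxytocin_only"` (RCS logistic on the biomarker alone) or
#'   `"combined"` (elastic net on oxytocin spline + leptin + BMI + waist
#'   circumference + HSI + VAI + a PCA-derived EDE-Q component).
#' @param include_edeq_component Keep the EDE-Q PCA component among the
#'   combined model's predictors. The component summarizes subscales of
#'   the same instrument that defines the outcome, which is circular; it
#'   is included by default to mirror the published model, and this flag
#'   exposes the non-circular alternative.
#' @param knots_k Knot count for the oxytocin spline (re-placed on each
#'   training split).
#' @param alpha_grid Elastic-net mixing values searched.
#' @param n_lambda,lambda_min_ratio Penalty path: `n_lambda` log-spaced
#'   values from the data-derived lambda_max down to
#'   `lambda_max * lambda_min_ratio`.
#' @return Object of class `phenospline_modelspec`.
#' @export
model_spec <- function(id = c("oxytocin_only", "combined"),
                       include_edeq_component = TRUE,
                       knots_k = 4,
                       alpha_grid = seq(0.1, 1, by = 0.1),
                       n_lambda = 50, lambda_min_ratio = 1e-4) {
  id <- match.arg(id)
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("alpha values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(id = id,
                 include_edeq_component = include_edeq_component,
                 knots_k = knots_k, alpha_grid = alpha_grid,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio),
            class = "phenospline_modelspec")
}

.edeq_subscales <- c("edeq_restraint", "edeq_eating_concern",
                     "edeq_shape_concern", "edeq_weight_concern")

# Learn preprocessing constants on training rows only: per-column median
# imputation values, oxytocin spline knots, EDE-Q PCA loadings, and
# centering/scaling constants of the assembled design.
.fit_preprocessor <- function(train, spec) {
  raw_cols <- if (spec$id == "oxytocin_only") "oxytocin" else {
    c("oxytocin", "leptin", "bmi", "wc", "hsi", "vai",
      if (spec$include_edeq_component) .edeq_subscales)
  }
  medians <- vapply(raw_cols, function(v) {
    stats::median(train[[v]], na.rm = TRUE)
  }, numeric(1))
  imp <- .impute(train, medians)
  knots <- place_knots(imp$oxytocin, k = spec$knots_k)
  pca <- NULL
  if (spec$id == "combined" && spec$include_edeq_component) {
    pca <- pca_scores(imp, .edeq_subscales, k = 1)
  }
  state <- list(spec = spec, medians = medians, knots = knots, pca = pca)
  D <- .assemble_design(state, imp)
  state$center <- colMeans(D)
  state$scale <- apply(D, 2, stats::sd)
  state$scale[state$scale == 0] <- 1
  class(state) <- "phenospline_preproc"
  state
}

.impute <- function(data, medians) {
  for (v in names(medians)) {
    x <- data[[v]]
    x[!is.finite(x)] <- medians[[v]]
    data[[v]] <- x
  }
  data
}

.assemble_design <- function(state, data) {
  B <- rcs_basis(data$oxytocin, state$knots)
  colnames(B) <- c("oxytocin", paste0("oxytocin_rcs",
                                      seq_len(ncol(B) - 1)))
  if (state$spec$id == "oxytocin_only") return(B)
  D <- cbind(B, leptin = data$leptin, bmi = data$bmi, wc = data$wc,
             hsi = data$hsi, vai = data$vai)
  if (!is.null(state$pca)) {
    D <- cbind(D, edeq_pc1 = drop(pca_project(state$pca, data)))
  }
  D
}

# Apply stored constants to any data; uses nothing learned from it.
.apply_preprocessor <- function(state, data) {
  imp <- .impute(data, state$medians)
  D <- .assemble_design(state, imp)
  scale(D, center = state$center, scale = state$scale)
}

#' Penalized logistic regression (elastic net) at fixed alpha/lambda
#'
#' Thin wrapper around [glmnet::glmnet()] on an already-standardized
#' design (`standardize = FALSE`, unpenalized intercept), with objective
#' `-(1/n) loglik + lambda (alpha |beta|_1 + (1 - alpha)/2 |beta|_2^2)`.
#'
#' @param X Numeric design matrix (columns standardized by the caller).
#' @param y Binary outcome.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param lambda Decreasing penalty sequence (a scalar is accepted).
#' @param thresh Coordinate-descent convergence threshold.
#' @return The `glmnet` fit object.
#' @export
enet_logistic <- function(X, y, alpha, lambda, thresh = 1e-12) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                 lambda = sort(lambda, decreasing = TRUE),
                 standardize = FALSE, thresh = thresh, maxit = 1e6)
}

#' Karush-Kuhn-Tucker residuals of an elastic-net logistic solution
#'
#' For coefficients `beta` at `(alpha, lambda)` on design `X`, the
#' stationarity conditions are `(1/n) X_j'(y - p) = lambda (1-alpha)
#' beta_j + lambda alpha sign(beta_j)` for active coordinates and
#' `|(1/n) X_j'(y - p)| <= lambda alpha` for zero coordinates; the
#' intercept score must vanish. Returns the largest violation.
#'
#' @param X Standardized design matrix.
#' @param y Binary outcome.
#' @param intercept,beta Fitted intercept and coefficient vector.
#' @param alpha,lambda The penalty at which the solution was computed.
#' @return Maximum KKT violation (0 at an exact solution).
#' @export
kkt_residuals <- function(X, y, intercept, beta, alpha, lambda) {
  n <- length(y)
  p_hat <- stats::plogis(drop(intercept + X %*% beta))
  score <- drop(crossprod(X, y - p_hat)) / n
  viol <- numeric(length(beta))
  active <- beta != 0
  viol[active] <- abs(score[active] - lambda * (1 - alpha) * beta[active] -
                        lambda * alpha * sign(beta[active]))
  viol[!active] <- pmax(abs(score[!active]) - lambda * alpha, 0)
  max(c(viol, abs(mean(y - p_hat))))
}

.lambda_path <- function(X, y, alpha, n_lambda, min_ratio) {
  n <- length(y)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / (n * max(alpha, 1e-3))
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
}

#' Fit one outer fold: within-fold preprocessing and tuning
#'
#' Learns the preprocessing state on the outer-training rows, and for the
#' combined model tunes `(lambda, alpha)` by mean inner-fold AUC — with
#' preprocessing refitted inside each inner-training split — then refits
#' on the full outer-training set at the selected penalty. The
#' oxytocin-only model is an unpenalized RCS logistic fit with knots
#' placed on the training split.
#'
#' @param train Training data.frame (must carry the model's raw columns;
#'   `hsi`/`vai` are computed via [add_metabolic_indices()] upstream).
#' @param y_train Binary outcome for the training rows.
#' @param spec A [model_spec()].
#' @param inner_fold Inner fold id per training row (from the fold plan),
#'   or NULL to skip tuning (oxytocin-only model ignores it).
#' @return List of class `phenospline_fold_fit`: `preprocessor`, `model`
#'   (`phenospline_rcs` or glmnet fit), `alpha`, `lambda`, `kkt`,
#'   `inner_auc`.
#' @export
fit_fold <- function(train, y_train, spec, inner_fold = NULL) {
  state <- .fit_preprocessor(train, spec)
  if (spec$id == "oxytocin_only") {
    imp <- .impute(train, state$medians)
    model <- suppressWarnings(
      fit_rcs_logistic(y_train, imp$oxytocin, spec = state$knots))
    return(structure(list(preprocessor = state, model = model,
                          alpha = NA_real_, lambda = NA_real_,
                          kkt = NA_real_, inner_auc = NA_real_),
                     class = "phenospline_fold_fit"))
  }
  D <- .apply_preprocessor(state, train)
  best <- list(auc = -Inf, alpha = NA, lambda = NA)
  for (a in spec$alpha_grid) {
    path <- .lambda_path(D, y_train, a, spec$n_lambda,
                         spec$lambda_min_ratio)
    if (is.null(inner_fold)) {
      sel <- list(auc = 0, lambda = path[length(path)])
      if (sel$auc >= best$auc) best <- list(auc = sel$auc, alpha = a,
                                            lambda = sel$lambda)
      next
    }
    folds <- sort(unique(inner_fold[!is.na(inner_fold)]))
    auc_mat <- matrix(NA_real_, nrow = length(folds), ncol = length(path))
    for (fi in seq_along(folds)) {
      tr <- which(!is.na(inner_fold) & inner_fold != folds[fi])
      va <- which(!is.na(inner_fold) & inner_fold == folds[fi])
      st_in <- .fit_preprocessor(train[tr, , drop = FALSE], spec)
      Din <- .apply_preprocessor(st_in, train[tr, , drop = FALSE])
      Dva <- .apply_preprocessor(st_in, train[va, , drop = FALSE])
      fit_in <- tryCatch(
        enet_logistic(Din, y_train[tr], a, path, thresh = 1e-9),
        error = function(e) NULL)
      if (is.null(fit_in)) next
      pv <- stats::predict(fit_in, Dva, type = "response",
                           s = sort(path, decreasing = TRUE))
      lam_used <- sort(path, decreasing = TRUE)
      for (li in seq_along(lam_used)) {
        if (li > ncol(pv)) break
        if (length(unique(y_train[va])) < 2) next
        auc_mat[fi, li] <- auc(pv[, li], y_train[va])
      }
    }
    mean_auc <- colMeans(auc_mat, na.rm = TRUE)
    lam_used <- sort(path, decreasing = TRUE)
    ok <- is.finite(mean_auc)
    if (!any(ok)) next
    bi <- which(mean_auc == max(mean_auc[ok]))[1]
    if (mean_auc[bi] > best$auc) {
      best <- list(auc = mean_auc[bi], alpha = a, lambda = lam_used[bi])
    }
  }
  path_final <- sort(unique(c(.lambda_path(D, y_train, best$alpha,
                                           spec$n_lambda,
                                           spec$lambda_min_ratio),
                              best$lambda)), decreasing = TRUE)
  fit <- enet_logistic(D, y_train, best$alpha, path_final)
  cf <- stats::coef(fit, s = best$lambda, exact = FALSE)
  beta <- as.numeric(cf)[-1]
  intercept <- as.numeric(cf)[1]
  kkt <- kkt_residuals(D, y_train, intercept, beta, best$alpha,
                       best$lambda)
  structure(list(preprocessor = state, model = fit, alpha = best$alpha,
                 lambda = best$lambda, intercept = intercept, beta = beta,
                 kkt = kkt, inner_auc = best$auc),
            class = "phenospline_fold_fit")
}

#' Predict event probabilities from a fitted fold
#'
#' @param fold_fit A `phenospline_fold_fit`.
#' @param newdata Data to score; only stored preprocessing constants are
#'   used.
#' @return Probability vector.
#' @export
predict_fold <- function(fold_fit, newdata) {
  state <- fold_fit$preprocessor
  if (state$spec$id == "oxytocin_only") {
    imp <- .impute(newdata, state$medians)
    return(rcs_predict(fold_fit$model, imp$oxytocin))
  }
  D <- .apply_preprocessor(state, newdata)
  stats::plogis(drop(fold_fit$intercept + D %*% fold_fit$beta))
}

#' Collect out-of-fold predictions
#'
#' Runs the nested cross-validation loop: for each outer fold, fits the
#' model (with within-fold preprocessing and tuning) on the training
#' split and scores the held-out split, so every participant is predicted
#' exactly once by a model never exposed to them.
#'
#' @param cohort Cohort data.frame; `hsi`/`vai` columns are computed on
#'   the fly if absent (row-wise index formulas, no leakage).
#' @param outcomes Binary outcome vector aligned with `cohort`; defaults
#'   to `edeq_global >= 2.5`.
#' @param specs List of [model_spec()] objects.
#' @param plan A [make_fold_plan()] plan covering the cohort.
#' @return Object of class `phenospline_oof`: `predictions` (data.frame
#'   `id`, `fold`, `y`, one probability column per model), `fold_fits`
#'   (per model, per fold), `plan`.
#' @export
collect_oof <- function(cohort, outcomes = NULL, specs, plan) {
  if (is.null(outcomes)) {
    outcomes <- as.integer(cohort$edeq_global >= 2.5)
  }
  y <- as.integer(outcomes)
  if (plan$n != nrow(cohort)) stop("fold plan does not cover the cohort",
                                   call. = FALSE)
  if (!all(c("hsi", "vai") %in% names(cohort)) &&
      any(vapply(specs, function(s) s$id == "combined", logical(1)))) {
    cohort <- add_metabolic_indices(cohort)
  }
  preds <- data.frame(id = seq_len(plan$n), fold = plan$outer, y = y)
  fold_fits <- list()
  for (spec in specs) {
    p_oof <- rep(NA_real_, plan$n)
    fits <- vector("list", plan$outer_k)
    for (f in seq_len(plan$outer_k)) {
      tr <- which(plan$outer != f)
      te <- which(plan$outer == f)
      fits[[f]] <- fit_fold(cohort[tr, , drop = FALSE], y[tr], spec,
                            inner_fold = plan$inner[[f]][tr])
      p_oof[te] <- predict_fold(fits[[f]], cohort[te, , drop = FALSE])
    }
    preds[[paste0("p_", spec$id)]] <- p_oof
    fold_fits[[spec$id]] <- fits
  }
  structure(list(predictions = preds, fold_fits = fold_fits, plan = plan),
            class = "phenospline_oof")
}
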