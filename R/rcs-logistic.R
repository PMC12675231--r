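# Restricted cubic spline basis, ML logistic fitting, and dose-response
# curves with bootstrap confidence bands.

#' Place spline knots at quantiles
#'
#' Default placement for k = 4 uses quantile probabilities
#' (0.05, 0.35, 0.65, 0.95); for other k the probabilities are spread
#' symmetrically between 0.05 and 0.95. Quantiles are type 7 (linear
#' interpolation).
#'
#' @param x Biomarker values.
#' @param k Knot count, 3 to 5.
#' @param probs Optional explicit quantile probabilities (length k).
#' @return Object of class `phenospline_knots`: `knots` (strictly
#'   increasing), `k`, `probs`.
#' @export
place_knots <- function(x, k = 4, probs = NULL) {
  x <- x[is.finite(x)]
  if (k < 3 || k > 5) stop("knot count k must be 3, 4 or 5", call. = FALSE)
  if (is.null(probs)) {
    probs <- if (k == 4) c(0.05, 0.35, 0.65, 0.95) else
      seq(0.05, 0.95, length.out = k)
  }
  if (length(probs) != k) stop("probs must have length k", call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < k) {
    stop("too few distinct values to host ", k, " knots", call. = FALSE)
  }
  kn <- if (length(ux) == k) ux else
    stats::quantile(x, probs, type = 7, names = FALSE)
  if (any(diff(kn) <= 0)) {
    stop("coincident knots at the requested quantiles; reduce k",
         call. = FALSE)
  }
  structure(list(knots = kn, k = k, probs = probs),
            class = "phenospline_knots")
}

#' Restricted cubic spline basis
#'
#' Natural cubic spline basis with k knots: column 1 is x itself; for
#' j = 1..k-2 the nonlinear column is
#' \deqn{C_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#' The resulting function space is C2-continuous and linear beyond the
#' boundary knots; the `(t_k - t_1)^2` scaling keeps the design
#' well-conditioned.
#'
#' @param x Numeric vector.
#' @param spec A `phenospline_knots` object from [place_knots()].
#' @return Matrix with k - 1 columns (`x`, `rcs1`, ..., `rcs(k-2)`).
#' @export
rcs_basis <- function(x, spec) {
  if (!inherits(spec, "phenospline_knots")) {
    stop("`spec` must come from place_knots()", call. = FALSE)
  }
  t <- spec$knots
  k <- spec$k
  scale2 <- (t[k] - t[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- vapply(seq_len(k - 2), function(j) {
    (pos3(x - t[j]) -
       pos3(x - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
       pos3(x - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) / scale2
  }, numeric(length(x)))
  out <- cbind(x, matrix(cols, nrow = length(x)))
  colnames(out) <- c("x", paste0("rcs", seq_len(k - 2)))
  out
}

#' Fit a restricted-cubic-spline logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on the RCS
#' basis of a biomarker, via IRLS ([stats::glm()] with a tight convergence
#' tolerance). The fit is checked for convergence (score norm), and for
#' separation (absolute standardized coefficient > 15 or perfect
#' in-sample classification), which is flagged with a warning rather than
#' an error.
#'
#' @param y Binary outcome (0/1); both classes must be present.
#' @param x Biomarker values.
#' @param spec Knot specification from [place_knots()]; defaults to 4
#'   knots placed on `x`.
#' @return Object of class `phenospline_rcs`: `coef`, `spec`, `glm_fit`,
#'   `converged`, `score_norm`, `separation`, `log_lik`, `n`.
#' @export
fit_rcs_logistic <- function(y, x, spec = NULL) {
  ok <- is.finite(x) & is.finite(y)
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2) stop("both outcome classes must be present",
                                  call. = FALSE)
  if (is.null(spec)) spec <- place_knots(x)
  B <- rcs_basis(x, spec)
  dat <- data.frame(y = y, B)
  fm <- stats::as.formula(paste("y ~", paste(colnames(B), collapse = " + ")))
  fit <- stats::glm(fm, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  X <- stats::model.matrix(fit)
  p_hat <- stats::fitted(fit)
  score <- drop(crossprod(X, y - p_hat))
  score_norm <- sqrt(sum(score^2))
  coef_std <- stats::coef(fit)[-1] * apply(X[, -1, drop = FALSE], 2, stats::sd)
  perfect <- all((p_hat > 0.5) == (y == 1)) &&
    (min(p_hat[y == 1], 1) > 0.99 || max(p_hat[y == 0], 0) < 0.01)
  separation <- any(abs(coef_std) > 15, na.rm = TRUE) || perfect
  if (separation) {
    warning("possible separation: coefficients may be unstable",
            call. = FALSE)
  }
  structure(list(coef = stats::coef(fit), spec = spec, glm_fit = fit,
                 converged = fit$converged && score_norm < 1e-6,
                 score_norm = score_norm, separation = separation,
                 log_lik = as.numeric(stats::logLik(fit)), n = length(y)),
            class = "phenospline_rcs")
}

#' Predicted event probability from an RCS logistic model
#'
#' @param model A `phenospline_rcs` fit.
#' @param x Biomarker values at which to predict.
#' @return Vector of probabilities in (0, 1).
#' @export
rcs_predict <- function(model, x) {
  B <- rcs_basis(x, model$spec)
  eta <- drop(cbind(1, B) %*% model$coef)
  stats::plogis(eta)
}

#' Dose-response curve with bootstrap confidence bands
#'
#' Evaluates the fitted probability over a biomarker grid and surrounds it
#' with pointwise percentile bands from B case-resampled refits (knots
#' held fixed at the point-estimate placement, so the band is conditional
#' on the knot locations). Replicates whose refit fails (error, a
#' single-class resample, or non-convergence) are dropped and counted.
#'
#' @param model A `phenospline_rcs` fit.
#' @param data Data.frame (or list) with elements/columns `y` and `x`
#'   holding the original outcome and biomarker.
#' @param grid Biomarker grid; defaults to 200 points across the observed
#'   range.
#' @param B Bootstrap replicates (>= 100).
#' @param level Band level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @return Object of class `phenospline_curve`: data.frame `curve`
#'   (`x`, `fit`, `lower`, `upper`), `n_failed`, `B`, `level`, `model`.
#' @export
dose_response <- function(model, data, grid = NULL, B = 2000,
                          level = 0.95, seed = 1) {
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  y <- data$y; x <- data$x
  ok <- is.finite(x) & is.finite(y)
  y <- y[ok]; x <- x[ok]
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 200)
  fit_curve <- rcs_predict(model, grid)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(y)
  boot <- matrix(NA_real_, nrow = B, ncol = length(grid))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      suppressWarnings(fit_rcs_logistic(y[idx], x[idx], spec = model$spec)),
      error = function(e) NULL)
    if (is.null(rep_fit)) { n_failed <- n_failed + 1L; next }
    boot[b, ] <- rcs_predict(rep_fit, grid)
  }
  alpha <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, type = 7)
  curve <- data.frame(x = grid, fit = fit_curve,
                      lower = pmin(qs[1, ], fit_curve),
                      upper = pmax(qs[2, ], fit_curve))
  structure(list(curve = curve, n_failed = n_failed, B = B, level = level,
                 model = model, boot = boot, y = y, x = x),
            class = "phenospline_curve")
}

#' Plot a dose-response curve
#'
#' Fitted probability with its bootstrap band and rug ticks for observed
#' positives (top) and negatives (bottom).
#'
#' @param x A `phenospline_curve` object.
#' @param p_star Optional probability threshold drawn as a dotted line.
#' @param cutoff Optional biomarker cutoff drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.phenospline_curve <- function(x, p_star = NULL, cutoff = NULL, ...) {
  cv <- x$curve
  g <- ggplot2::ggplot(cv, ggplot2::aes(x = x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = fit)) +
    ggplot2::geom_rug(data = data.frame(v = x$x[x$y == 1]),
                      ggplot2::aes(x = v), inherit.aes = FALSE,
                      sides = "t", alpha = 0.5) +
    ggplot2::geom_rug(data = data.frame(v = x$x[x$y == 0]),
                      ggplot2::aes(x = v), inherit.aes = FALSE,
                      sides = "b", alpha = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Biomarker", y = "Predicted event probability")
  if (!is.null(p_star)) {
    g <- g + ggplot2::geom_hline(yintercept = p_star, linetype = 3)
  }
  if (!is.null(cutoff)) {
    g <- g + ggplot2::geom_vline(xintercept = cutoff, linetype = 2)
  }
  g
}
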