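# Out-of-fold discrimination, calibration, operating-point selection,
# paired bootstrap AUC comparison, and inversion of a probability
# threshold to the biomarker scale.

.check_binary <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2) stop("both outcome classes must be present",
                                  call. = FALSE)
  y
}

.local_seed <- function(seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  old_seed
}

.restore_seed <- function(old_seed) {
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Fraction of (positive, negative) pairs ordered correctly by the
#' predictions, with half credit for ties; computed from average ranks,
#' so it agrees exactly with brute-force pair concordance.
#'
#' @param predictions Numeric prediction vector (any monotone score).
#' @param outcomes Binary outcome vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(predictions, outcomes) {
  y <- .check_binary(outcomes)
  r <- rank(predictions)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @param predictions Probabilities in `[0, 1]`.
#' @param outcomes Binary outcomes.
#' @return Brier score in `[0, 1]`.
#' @export
brier <- function(predictions, outcomes) {
  if (any(predictions < 0 | predictions > 1)) {
    stop("predictions must lie in [0, 1]", call. = FALSE)
  }
  mean((predictions - as.integer(outcomes))^2)
}

#' ROC curve with bootstrap AUC interval
#'
#' @param predictions,outcomes As in [auc()].
#' @param B Bootstrap replicates for the AUC percentile CI.
#' @param level CI level.
#' @param seed RNG seed.
#' @return Object of class `phenospline_roc`: `points` (threshold, FPR,
#'   TPR, monotone nondecreasing), `auc`, `auc_ci`, `brier`, `n`.
#' @export
roc_result <- function(predictions, outcomes, B = 2000, level = 0.95,
                       seed = 1) {
  y <- .check_binary(outcomes)
  th <- c(Inf, sort(unique(predictions), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pos <- predictions >= t
    c(fpr = sum(pos & y == 0) / sum(y == 0),
      tpr = sum(pos & y == 1) / sum(y == 1))
  }, numeric(2)))
  points <- data.frame(threshold = th, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  a <- auc(predictions, y)
  old <- .local_seed(seed); on.exit(.restore_seed(old))
  n <- length(y)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc(predictions[idx], y[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  structure(list(points = points, auc = a, auc_ci = ci,
                 brier = brier(predictions, y), n = n, B = B),
            class = "phenospline_roc")
}

# Sensitivity and specificity at threshold t (positive <=> p >= t).
.sens_spec <- function(predictions, y, t) {
  pos <- predictions >= t
  c(sens = sum(pos & y == 1) / sum(y == 1),
    spec = sum(!pos & y == 0) / sum(y == 0))
}

# Exhaustive scan over observed prediction values; ties in J broken
# toward higher specificity (the larger threshold).
.youden_scan <- function(predictions, y) {
  th <- sort(unique(predictions))
  ss <- t(vapply(th, function(t) .sens_spec(predictions, y, t),
                 numeric(2)))
  J <- ss[, "sens"] + ss[, "spec"] - 1
  best <- which(J == max(J))
  pick <- best[length(best)]
  list(p_star = th[pick], J = unname(J[pick]),
       sens = unname(ss[pick, "sens"]), spec = unname(ss[pick, "spec"]))
}

#' Youden-optimal operating point with bootstrap intervals
#'
#' Scans all observed prediction values for the threshold maximizing
#' `J = sensitivity + specificity - 1` (ties broken toward higher
#' specificity) and attaches percentile bootstrap CIs for sensitivity and
#' specificity, re-estimating the threshold within each case-resampled
#' replicate.
#'
#' @param predictions,outcomes As in [auc()].
#' @param B Bootstrap replicates.
#' @param level CI level.
#' @param seed RNG seed.
#' @return Object of class `phenospline_youden`: `p_star`, `J`, `sens`,
#'   `spec`, `sens_ci`, `spec_ci`, `B`.
#' @export
youden_point <- function(predictions, outcomes, B = 2000, level = 0.95,
                         seed = 1) {
  y <- .check_binary(outcomes)
  pt <- .youden_scan(predictions, y)
  old <- .local_seed(seed); on.exit(.restore_seed(old))
  n <- length(y)
  reps <- matrix(NA_real_, nrow = B, ncol = 2)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) next
    sb <- .youden_scan(predictions[idx], y[idx])
    reps[b, ] <- c(sb$sens, sb$spec)
  }
  alpha <- (1 - level) / 2
  structure(list(p_star = pt$p_star, J = pt$J, sens = pt$sens,
                 spec = pt$spec,
                 sens_ci = stats::quantile(reps[, 1], c(alpha, 1 - alpha),
                                           na.rm = TRUE, names = FALSE),
                 spec_ci = stats::quantile(reps[, 2], c(alpha, 1 - alpha),
                                           na.rm = TRUE, names = FALSE),
                 B = B),
            class = "phenospline_youden")
}

#' Paired bootstrap comparison of two models' AUCs
#'
#' Case-resamples the shared participants B times, recomputes both AUCs
#' on each resample, and reports the percentile CI of the difference
#' (model B minus model A) and a two-sided bootstrap p-value
#' `p = 2 min(frac(delta <= 0), frac(delta >= 0))` with a +1 continuity
#' correction in numerator and denominator, capped at 1.
#'
#' @param pred_a,pred_b Prediction vectors for the same participants.
#' @param outcomes Shared binary outcome vector.
#' @param B Bootstrap replicates (>= 1).
#' @param level CI level.
#' @param seed RNG seed.
#' @return Object of class `phenospline_delta_auc`: `delta` (point
#'   estimate), `ci`, `p`, `auc_a`, `auc_b`, `B`, `n_dropped`.
#' @export
paired_delta_auc <- function(pred_a, pred_b, outcomes, B = 2000,
                             level = 0.95, seed = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (length(pred_a) != length(pred_b) ||
      length(pred_a) != length(outcomes)) {
    stop("prediction sets must cover the same participants", call. = FALSE)
  }
  y <- .check_binary(outcomes)
  a0 <- auc(pred_a, y); b0 <- auc(pred_b, y)
  old <- .local_seed(seed); on.exit(.restore_seed(old))
  n <- length(y)
  deltas <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) next
    deltas[b] <- auc(pred_b[idx], y[idx]) - auc(pred_a[idx], y[idx])
  }
  used <- deltas[!is.na(deltas)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(used, c(alpha, 1 - alpha), names = FALSE)
  m <- length(used)
  p <- min(1, 2 * min((1 + sum(used <= 0)) / (m + 1),
                      (1 + sum(used >= 0)) / (m + 1)))
  structure(list(delta = b0 - a0, ci = ci, p = p, auc_a = a0, auc_b = b0,
                 B = B, n_dropped = B - m),
            class = "phenospline_delta_auc")
}

#' Logistic recalibration of predicted probabilities
#'
#' Calibration slope = coefficient of `logit(p_hat)` in a logistic refit
#' of the outcome; calibration intercept = intercept of a logistic refit
#' with `logit(p_hat)` as a fixed offset. Slope 1 and intercept 0
#' indicate perfect calibration. Also returns a 10-bin equal-count
#' reliability table. Probabilities are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param predictions Probabilities.
#' @param outcomes Binary outcomes.
#' @param bins Number of equal-count reliability bins.
#' @return Object of class `phenospline_calibration`: `intercept`,
#'   `slope`, their SEs, `reliability` (bin table), `degenerate`.
#' @export
calibration <- function(predictions, outcomes, bins = 10) {
  y <- .check_binary(outcomes)
  p <- pmin(pmax(predictions, 1e-6), 1 - 1e-6)
  if (stats::sd(p) == 0) {
    return(structure(list(intercept = NA_real_, slope = NA_real_,
                          intercept_se = NA_real_, slope_se = NA_real_,
                          reliability = NULL, degenerate = TRUE),
                     class = "phenospline_calibration"))
  }
  lp <- stats::qlogis(p)
  slope_fit <- stats::glm(y ~ lp, family = stats::binomial())
  int_fit <- stats::glm(y ~ 1, offset = lp, family = stats::binomial())
  qbreaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = bins + 1),
                                    type = 7))
  bin_id <- cut(p, qbreaks, include.lowest = TRUE)
  rel <- data.frame(
    bin = levels(bin_id),
    n = as.integer(table(bin_id)),
    mean_pred = as.numeric(tapply(p, bin_id, mean)),
    obs_rate = as.numeric(tapply(y, bin_id, mean))
  )
  structure(list(
    intercept = unname(stats::coef(int_fit)[1]),
    slope = unname(stats::coef(slope_fit)["lp"]),
    intercept_se = unname(sqrt(stats::vcov(int_fit)[1, 1])),
    slope_se = unname(sqrt(stats::vcov(slope_fit)["lp", "lp"])),
    reliability = rel, degenerate = FALSE),
    class = "phenospline_calibration")
}

# All crossings of a piecewise-linear curve with level p_star, with
# linear interpolation and crossing direction.
.find_crossings <- function(x, p, p_star) {
  s <- p - p_star
  out <- data.frame(x = numeric(0), direction = character(0))
  # exact grid hits
  hits <- which(s == 0)
  for (i in seq_along(s)[-length(s)]) {
    if (s[i] == 0) next
    if (s[i] > 0 && s[i + 1] < 0) {
      xc <- x[i] + (x[i + 1] - x[i]) * s[i] / (s[i] - s[i + 1])
      out <- rbind(out, data.frame(x = xc, direction = "down"))
    } else if (s[i] < 0 && s[i + 1] > 0) {
      xc <- x[i] + (x[i + 1] - x[i]) * (-s[i]) / (s[i + 1] - s[i])
      out <- rbind(out, data.frame(x = xc, direction = "up"))
    }
  }
  for (i in hits) {
    dir <- if (i > 1 && s[i - 1] > 0) "down"
    else if (i < length(s) && s[i + 1] > 0) "up"
    else if (i < length(s) && s[i + 1] < 0) "down"
    else "touch"
    out <- rbind(out, data.frame(x = x[i], direction = dir))
  }
  out[order(out$x), , drop = FALSE]
}

#' Map a probability threshold to the biomarker scale
#'
#' Finds where the fitted dose-response curve crosses `p_star` (sign
#' change with linear interpolation between grid points). The selected
#' crossing is the smallest biomarker value at which the predicted
#' probability falls from above to below `p_star` — risk decreasing with
#' rising biomarker. All crossings are reported. The percentile CI of the
#' selected crossing is taken over the curve's stored bootstrap
#' replicates, inverting each refitted replicate curve; replicates
#' without a down-crossing are counted and excluded. An absent crossing
#' in the point estimate yields an empty mapping with `found = FALSE`,
#' not an error.
#'
#' @param curve A [dose_response()] result.
#' @param p_star Probability threshold in (0, 1).
#' @param level CI level.
#' @return Object of class `phenospline_cutoff`: `p_star`, `crossings`
#'   (all, with direction), `cutoff` (selected or NA), `ci`, `found`,
#'   `n_no_crossing`, `grid_step`.
#' @export
map_threshold_to_biomarker <- function(curve, p_star, level = 0.95) {
  if (p_star <= 0 || p_star >= 1) stop("p_star must lie in (0, 1)",
                                       call. = FALSE)
  cv <- curve$curve
  crossings <- .find_crossings(cv$x, cv$fit, p_star)
  down <- crossings[crossings$direction == "down", , drop = FALSE]
  found <- nrow(down) > 0
  cutoff <- if (found) min(down$x) else NA_real_
  boot_cut <- apply(curve$boot, 1, function(pb) {
    if (any(is.na(pb))) return(NA_real_)
    cr <- .find_crossings(cv$x, pb, p_star)
    dn <- cr[cr$direction == "down", , drop = FALSE]
    if (nrow(dn) == 0) NA_real_ else min(dn$x)
  })
  n_missing <- sum(is.na(boot_cut))
  alpha <- (1 - level) / 2
  ci <- if (all(is.na(boot_cut))) c(NA_real_, NA_real_) else {
    stats::quantile(boot_cut, c(alpha, 1 - alpha), na.rm = TRUE,
                    names = FALSE)
  }
  structure(list(p_star = p_star, crossings = crossings, cutoff = cutoff,
                 ci = ci, found = found, n_no_crossing = n_missing,
                 grid_step = mean(diff(cv$x))),
            class = "phenospline_cutoff")
}

#' Plot ROC curves with operating points
#'
#' @param rocs Named list of `phenospline_roc` objects.
#' @param points Optional named list of `phenospline_youden` objects to
#'   mark on the matching curves.
#' @return A ggplot object.
#' @export
plot_roc <- function(rocs, points = NULL) {
  dfs <- do.call(rbind, lapply(names(rocs), function(nm) {
    cbind(rocs[[nm]]$points, model = nm)
  }))
  g <- ggplot2::ggplot(dfs, ggplot2::aes(x = fpr, y = tpr,
                                         colour = model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity")
  if (!is.null(points)) {
    dots <- do.call(rbind, lapply(names(points), function(nm) {
      data.frame(fpr = 1 - points[[nm]]$spec, tpr = points[[nm]]$sens,
                 model = nm)
    }))
    g <- g + ggplot2::geom_point(data = dots, size = 2)
  }
  g
}
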