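# Decision-curve analysis: net benefit versus treat-all and treat-none.

#' Net benefit curve
#'
#' For each threshold probability `p_t`, a participant is classified
#' positive when the predicted probability is at least `p_t`, and
#' `NB(p_t) = TP/n - (FP/n) p_t / (1 - p_t)`. Treat-none has net benefit
#' 0 everywhere; treat-all has `pi - (1 - pi) p_t / (1 - p_t)` where `pi`
#' is the sample prevalence (so it crosses 0 exactly at `p_t = pi`).
#'
#' @param predictions Named list of probability vectors (one per model),
#'   or a single vector.
#' @param outcomes Binary outcome vector.
#' @param thresholds Threshold grid in (0, 1); default 0.05 to 0.95 by
#'   0.01.
#' @return Object of class `phenospline_dca`: `curve` (long data.frame
#'   `threshold`, `strategy`, `net_benefit`), `prevalence`, `n`.
#' @export
net_benefit <- function(predictions, outcomes,
                        thresholds = seq(0.05, 0.95, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.list(predictions)) predictions <- list(model = predictions)
  y <- as.integer(outcomes)
  n <- length(y)
  prev <- mean(y)
  nb_model <- function(p, t) {
    pos <- p >= t
    tp <- sum(pos & y == 1)
    fp <- sum(pos & y == 0)
    tp / n - (fp / n) * t / (1 - t)
  }
  rows <- lapply(names(predictions), function(nm) {
    data.frame(threshold = thresholds, strategy = nm,
               net_benefit = vapply(thresholds, function(t) {
                 nb_model(predictions[[nm]], t)
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(
    data.frame(threshold = thresholds, strategy = "treat_all",
               net_benefit = prev - (1 - prev) * thresholds /
                 (1 - thresholds), stringsAsFactors = FALSE),
    data.frame(threshold = thresholds, strategy = "treat_none",
               net_benefit = 0, stringsAsFactors = FALSE)))
  structure(list(curve = do.call(rbind, rows), prevalence = prev, n = n),
            class = "phenospline_dca")
}

#' Plot a decision curve
#'
#' Net benefit against threshold probability for each strategy, with a
#' vertical line at the cohort prevalence and an optional operating-point
#' marker.
#'
#' @param x A `phenospline_dca` object.
#' @param mark Optional list `list(threshold = , strategy = )` marking an
#'   operating point on one curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.phenospline_dca <- function(x, mark = NULL, ...) {
  g <- ggplot2::ggplot(x$curve,
                       ggplot2::aes(x = threshold, y = net_benefit,
                                    colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = x$prevalence, linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(x$prevalence + 0.05,
                                                 0.1))) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit")
  if (!is.null(mark)) {
    sub <- x$curve[x$curve$strategy == mark$strategy, ]
    nb <- stats::approx(sub$threshold, sub$net_benefit,
                        xout = mark$threshold)$y
    g <- g + ggplot2::geom_point(
      data = data.frame(threshold = mark$threshold, net_benefit = nb,
                        strategy = mark$strategy),
      colour = "red", size = 2.5)
  }
  g
}
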