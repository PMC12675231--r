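# Nonparametric group statistics: normality gate, Kruskal-Wallis, Dunn's
# post hoc test with tie correction, multiplicity control, effect sizes,
# Spearman matrices and prevalence tables.

#' Shapiro-Wilk normality gate
#'
#' @param x Numeric vector, 3 <= n <= 5000 after dropping non-finite values.
#' @param alpha Gate level (default 0.05).
#' @return List with `statistic`, `p`, `is_normal` (p > alpha) and
#'   `degenerate` (TRUE for a constant vector, where the test is undefined).
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) stop("normality gate needs n >= 3", call. = FALSE)
  if (length(x) > 5000) stop("normality gate supports n <= 5000", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, is_normal = NA,
                degenerate = TRUE))
  }
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value > alpha, degenerate = FALSE)
}

.check_groups <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("every group must be non-empty",
                                    call. = FALSE)
  list(values = values, groups = groups)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k - 1 df (delegates to
#' [stats::kruskal.test()]). A fully tied sample has H = 0 and is flagged
#' degenerate.
#'
#' @param values Numeric vector.
#' @param groups Group labels, coercible to factor; every level non-empty.
#' @return List with `H`, `df`, `p`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups) {
  d <- .check_groups(values, groups)
  if (stats::sd(d$values) == 0) {
    return(list(H = 0, df = nlevels(d$groups) - 1L, p = NA_real_,
                degenerate = TRUE))
  }
  kw <- stats::kruskal.test(d$values, d$groups)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, degenerate = FALSE)
}

#' Dunn's post hoc test
#'
#' Pairwise rank comparisons following a Kruskal-Wallis test, using the
#' tie-corrected standard error
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))` over tie groups of size
#' t. Two-sided p-values from the standard normal; adjusted per `adjust`.
#' With two groups and no ties, `z^2` equals the Kruskal-Wallis H.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param adjust `"bonferroni"` (default, matching the primary analysis) or
#'   `"bh"` for Benjamini-Hochberg FDR.
#' @return Data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p`, `p_adjusted`, `median_diff` (median of group1 minus group2) and
#'   `cohens_d`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  d <- .check_groups(values, groups)
  values <- d$values; groups <- d$groups
  N <- length(values)
  r <- rank(values)  # average ranks for ties
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    xi <- values[groups == i]; xj <- values[groups == j]
    data.frame(group1 = i, group2 = j, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               median_diff = stats::median(xi) - stats::median(xj),
               cohens_d = tryCatch(cohens_d(xi, xj), error = function(e) NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- adjust_pvalues(out$p, adjust)
  rownames(out) <- NULL
  out[, c("group1", "group2", "z", "p", "p_adjusted", "median_diff",
          "cohens_d")]
}

#' Multiplicity adjustment
#'
#' Bonferroni or Benjamini-Hochberg step-up adjustment (delegates to
#' [stats::p.adjust()]), with input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, capped at 1, significance ordering preserved.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Kruskal-Wallis screen across variables with FDR control
#'
#' Applies [kruskal_wallis()] to each variable, adjusts the p-values by
#' Benjamini-Hochberg across the variable family, and attaches Dunn post
#' hoc results for each variable.
#'
#' @param cohort Cohort data.frame.
#' @param variables Character vector of numeric columns to test.
#' @param group_col Grouping column name (default `"phenotype"`).
#' @param posthoc_adjust Adjustment for the Dunn pairs (default Bonferroni).
#' @return List with `tests` (variable, H, p, q, family size) and
#'   `posthoc` (named list of Dunn tables).
#' @export
compare_groups <- function(cohort, variables, group_col = "phenotype",
                           posthoc_adjust = c("bonferroni", "bh")) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  miss <- setdiff(c(variables, group_col), names(cohort))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  kw <- lapply(variables, function(v) {
    res <- kruskal_wallis(cohort[[v]], cohort[[group_col]])
    data.frame(variable = v, H = res$H, df = res$df, p = res$p,
               degenerate = res$degenerate, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, kw)
  ok <- !is.na(tests$p)
  tests$q <- NA_real_
  tests$q[ok] <- adjust_pvalues(tests$p[ok], "bh")
  tests$family_size <- sum(ok)
  posthoc <- lapply(variables, function(v) {
    dunn_posthoc(cohort[[v]], cohort[[group_col]], posthoc_adjust)
  })
  names(posthoc) <- variables
  list(tests = tests, posthoc = posthoc)
}

#' Spearman correlation matrix
#'
#' Pairwise-complete Spearman correlations with p-values from the
#' t-approximation `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df.
#' Constant columns yield NA with a flag.
#'
#' @param cohort Data.frame.
#' @param variables Columns to correlate (>= 4 complete pairs per cell).
#' @return List of matrices `rho`, `p`, `n`; attribute `flagged` names any
#'   constant columns.
#' @export
spearman_matrix <- function(cohort, variables) {
  miss <- setdiff(variables, names(cohort))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  k <- length(variables)
  rho <- p <- nmat <- matrix(NA_real_, k, k,
                             dimnames = list(variables, variables))
  flagged <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- cohort[[variables[i]]]; y <- cohort[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      nn <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nn
      if (nn < 4) stop("fewer than 4 complete pairs for ", variables[i],
                       " vs ", variables[j], call. = FALSE)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        flagged <- union(flagged, variables[c(i, j)][c(stats::sd(x[ok]) == 0,
                                                       stats::sd(y[ok]) == 0)])
        next
      }
      r <- stats::cor(x[ok], y[ok], method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      if (i == j) { p[i, j] <- NA_real_; next }
      if (abs(r) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tval <- r * sqrt((nn - 2) / (1 - r^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tval), nn - 2)
      }
    }
  }
  structure(list(rho = rho, p = p, n = nmat), flagged = flagged,
            class = "phenospline_cormat")
}

#' Prevalence of scores at or above instrument cutoffs
#'
#' @param cohort Data.frame of subscale scores.
#' @param cutoffs Named numeric vector mapping subscale column to cutoff,
#'   e.g. `c(edeq_weight_concern = 4.0)`; counting uses `>=`.
#' @return Data.frame: `subscale`, `cutoff`, `n_total`, `count`, `percent`.
#' @export
prevalence_table <- function(cohort, cutoffs) {
  miss <- setdiff(names(cutoffs), names(cohort))
  if (length(miss)) stop("unknown subscale(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(names(cutoffs), function(v) {
    x <- cohort[[v]]
    x <- x[is.finite(x)]
    cnt <- sum(x >= cutoffs[[v]])
    data.frame(subscale = v, cutoff = cutoffs[[v]], n_total = length(x),
               count = cnt,
               percent = if (length(x)) 100 * cnt / length(x) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's d with pooled SD
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Cohen's d; error if the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 observations",
                             call. = FALSE)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("pooled SD is zero; effect size undefined",
                     call. = FALSE)
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}
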