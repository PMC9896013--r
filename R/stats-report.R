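#' Two-sided Wilcoxon rank-sum test with normal approximation
#'
#' Rank-sum statistic of sample `a` within the pooled sample using midranks
#' for ties; the z-score uses the tie-corrected variance and a continuity
#' correction, and the two-sided p-value comes from the normal
#' approximation. Accuracy distributions from resampling experiments are
#' heavily tied and far from normal at high accuracy, which is exactly the
#' regime this rank-based test targets.
#'
#' @param a,b numeric samples (non-empty).
#' @return list `rank_sum` (of `a`), `z_score`, `p_two_sided`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  if (length(a) < 1 || length(b) < 1)
    stop_invalid("both samples must be non-empty")
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n2 + n1 + 1) / 2
  ties <- table(pooled)
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(rank_sum = w, z_score = 0, p_two_sided = 1))
  dev <- w - mu
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)  # continuity correction
  if (dev == 0) z <- 0
  list(rank_sum = w, z_score = z,
       p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Cohen's d effect size with confidence interval
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled sd, and a
#' normal-approximation CI using
#' `SE = sqrt((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param a,b numeric samples with >= 2 observations each.
#' @param ci_level confidence level (default 0.95).
#' @return list `d`, `ci_lower`, `ci_upper`; `d` is `Inf`-signed (with `NA`
#'   CI) when the pooled sd is zero but the means differ, 0 when both are
#'   identical.
#' @export
cohens_d <- function(a, b, ci_level = 0.95) {
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("both samples need >= 2 observations")
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    d <- if (diff == 0) 0 else sign(diff) * Inf
    return(list(d = d, ci_lower = NA_real_, ci_upper = NA_real_))
  }
  d <- diff / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(d = d, ci_lower = d - zq * se, ci_upper = d + zq * se)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param n_comparisons number of comparisons (>= 1).
#' @return `min(1, p * n_comparisons)`, vectorized over `p`.
#' @export
bonferroni <- function(p, n_comparisons) {
  if (n_comparisons < 1) stop_invalid("`n_comparisons` must be >= 1")
  pmin(1, p * n_comparisons)
}

#' Compare two accuracy distributions
#'
#' Bundles the rank-sum test, Cohen's d with CI, and the
#' Bonferroni-adjusted p-value into one report, the standard summary for
#' comparing identification accuracies across conditions.
#'
#' @param a,b accuracy samples (percent).
#' @param n_comparisons comparisons for the Bonferroni adjustment.
#' @param ci_level CI level for the effect size.
#' @return list of class `comparison_result`: `rank_sum`, `z_score`,
#'   `p_raw`, `p_bonferroni`, `effect_size_d`, `d_ci_lower`, `d_ci_upper`.
#' @export
compare_accuracies <- function(a, b, n_comparisons = 1, ci_level = 0.95) {
  w <- wilcoxon_ranksum(a, b)
  d <- cohens_d(a, b, ci_level)
  structure(list(rank_sum = w$rank_sum, z_score = w$z_score,
                 p_raw = w$p_two_sided,
                 p_bonferroni = bonferroni(w$p_two_sided, n_comparisons),
                 effect_size_d = d$d, d_ci_lower = d$ci_lower,
                 d_ci_upper = d$ci_upper),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison> rank sum %.4g, z = %.3g, p = %.3g (Bonferroni %.3g), d = %.3g [%.3g, %.3g]\n",
    x$rank_sum, x$z_score, x$p_raw, x$p_bonferroni, x$effect_size_d,
    x$d_ci_lower, x$d_ci_upper))
  invisible(x)
}

#' Violin-style distribution summary for plotting
#'
#' Median, quartiles and value frequencies of an accuracy distribution —
#' enough to redraw the usual violin/box summaries without shipping raw
#' repetitions.
#'
#' @param accuracies numeric vector (percent).
#' @return list `median`, `q1`, `q3`, `mean`, `sd`, `frequencies`
#'   (data frame `value`, `count`).
#' @export
accuracy_summary <- function(accuracies) {
  q <- stats::quantile(accuracies, c(0.25, 0.5, 0.75), names = FALSE)
  tab <- table(accuracies)
  list(median = q[2], q1 = q[1], q3 = q[3], mean = mean(accuracies),
       sd = stats::sd(accuracies),
       frequencies = data.frame(value = as.numeric(names(tab)),
                                count = as.integer(tab)))
}
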