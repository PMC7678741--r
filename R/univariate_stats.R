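#' Two-sided Wilcoxon rank-sum test between two groups of LFQ values
#'
#' Bilateral Wilcoxon (Mann-Whitney) rank-sum test of a single protein's
#' values between the cardioembolic (C) and atherothrombotic (A) groups.
#' The exact null distribution is enumerated when the smaller group has at
#' most 10 values and there are no ties; otherwise the normal approximation
#' with midrank tie correction and continuity correction is used.
#'
#' @param values_c,values_a numeric vectors of (log2) LFQ values; `NA`s
#'   (missing values) are dropped.
#' @param protein_id optional identifier carried into the result.
#' @return a `univariate_result` list: `protein_id`, `statistic` (rank-sum
#'   W of group A vs C as in [stats::wilcox.test]), `p_value`,
#'   `neg_log10_p`, `difference` (mean A - mean C), `n_valid_c`,
#'   `n_valid_a`, `untestable`. An empty group yields `untestable = TRUE`
#'   with `p_value = NA`.
#' @export
wilcoxon_rank_sum <- function(values_c, values_a, protein_id = NA_character_) {
  values_c <- values_c[!is.na(values_c)]
  values_a <- values_a[!is.na(values_a)]
  n_c <- length(values_c); n_a <- length(values_a)
  if (n_c == 0 || n_a == 0) {
    return(structure(
      list(protein_id = protein_id, statistic = NA_real_, p_value = NA_real_,
           neg_log10_p = NA_real_, difference = NA_real_,
           n_valid_c = n_c, n_valid_a = n_a, untestable = TRUE),
      class = "univariate_result"))
  }
  has_ties <- anyDuplicated(c(values_c, values_a)) > 0
  exact <- min(n_c, n_a) <= 10 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_c, alternative = "two.sided",
                exact = exact, correct = TRUE))
  # completely tied data degenerate the normal approximation (0/0): there is
  # no evidence against the null, so p = 1
  p <- if (is.na(wt$p.value)) 1 else min(wt$p.value, 1)
  structure(
    list(protein_id = protein_id, statistic = unname(wt$statistic),
         p_value = p, neg_log10_p = -log10(p),
         difference = mean(values_a) - mean(values_c),
         n_valid_c = n_c, n_valid_a = n_a, untestable = FALSE),
    class = "univariate_result")
}

#' Per-protein t statistics and volcano quantities
#'
#' Two-sample t-test per protein of a log2-scale LFQ matrix, computed on
#' valid values only (no imputation). The reported `difference` is oriented
#' as mean(log2 LFQ in A) - mean(log2 LFQ in C): proteins enriched in
#' cardioembolic thrombi have negative differences. Welch's
#' unequal-variance test is the default; `var_equal = TRUE` gives the
#' pooled-variance Student test. `neg_log10_p` uses base 10.
#'
#' Proteins with fewer than 2 valid values in either group are flagged
#' `untestable` and reported with `NA` statistics rather than dropped.
#'
#' @param x an [lfq_matrix] on the log2 scale.
#' @param min_fraction optional: apply [filter_min_valid()] with this
#'   fraction before testing.
#' @param var_equal pooled-variance Student test instead of Welch.
#' @param alpha significance threshold for the `significant` flag
#'   (unadjusted p; default 0.05).
#' @param adjust add a Benjamini-Hochberg `q_value` column.
#' @return data.frame with one row per protein: `protein_id`, `n_valid_a`,
#'   `n_valid_c`, `statistic`, `df`, `p_value`, optional `q_value`,
#'   `difference`, `neg_log10_p`, `significant`, `untestable`.
#' @export
welch_t_volcano <- function(x, min_fraction = NULL, var_equal = FALSE,
                            alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(x, "lfq_matrix"))
  if (!x$log2)
    .thrombo_error("precondition", "welch_t_volcano expects a log2-transformed matrix")
  if (!is.null(min_fraction))
    x <- filter_min_valid(x, min_fraction)$matrix

  in_a <- x$groups == "A"
  in_c <- x$groups == "C"
  stats_a <- .group_moments(x, in_a)
  stats_c <- .group_moments(x, in_c)

  diff <- stats_a$mean - stats_c$mean
  if (var_equal) {
    df <- stats_a$n + stats_c$n - 2
    sp2 <- ((stats_a$n - 1) * stats_a$var + (stats_c$n - 1) * stats_c$var) / df
    se <- sqrt(sp2 * (1 / stats_a$n + 1 / stats_c$n))
  } else {
    va <- stats_a$var / stats_a$n
    vc <- stats_c$var / stats_c$n
    se <- sqrt(va + vc)
    df <- (va + vc)^2 /
      (va^2 / (stats_a$n - 1) + vc^2 / (stats_c$n - 1))
  }
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df)
  # degenerate zero-variance cases: identical groups -> no evidence (p = 1);
  # zero variance with a real shift -> p underflows, clamp into (0, 1]
  zero_se <- is.finite(diff) & !is.na(se) & se == 0
  p[zero_se & diff == 0] <- 1
  tstat[zero_se & diff == 0] <- 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  untestable <- stats_a$n < 2 | stats_c$n < 2
  p[untestable] <- NA_real_
  tstat[untestable] <- NA_real_
  df[untestable] <- NA_real_

  out <- data.frame(
    protein_id = protein_ids(x),
    n_valid_a = stats_a$n, n_valid_c = stats_c$n,
    statistic = tstat, df = df, p_value = p,
    difference = ifelse(stats_a$n >= 1 & stats_c$n >= 1, diff, NA_real_),
    neg_log10_p = -log10(p),
    significant = !is.na(p) & p < alpha,
    untestable = untestable,
    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out <- out[, c("protein_id", "n_valid_a", "n_valid_c", "statistic", "df",
                   "p_value", "q_value", "difference", "neg_log10_p",
                   "significant", "untestable")]
  }
  out
}

.group_moments <- function(x, cols) {
  m <- x$intensities[, cols, drop = FALSE]
  v <- x$valid_mask[, cols, drop = FALSE]
  n <- rowSums(v)
  s <- rowSums(m, na.rm = TRUE)
  mean <- ifelse(n > 0, s / n, NA_real_)
  dev2 <- (m - mean)^2
  dev2[!v] <- NA
  var <- ifelse(n > 1, rowSums(dev2, na.rm = TRUE) / (n - 1), NA_real_)
  list(n = n, mean = mean, var = var)
}

#' Volcano plot of per-protein differences
#'
#' Scatter of group difference (log2, A - C) against -log10 p with the
#' significant proteins highlighted. Requires ggplot2.
#'
#' @param results data.frame from [welch_t_volcano()].
#' @param alpha significance threshold drawn as a horizontal line.
#' @param highlight optional protein IDs drawn in a third colour (e.g. the
#'   panel-search hits).
#' @return a ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.05, highlight = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_volcano requires ggplot2")
  d <- results[!results$untestable, , drop = FALSE]
  d$class <- ifelse(d$protein_id %in% highlight, "panel",
                    ifelse(d$significant, "significant", "ns"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$difference, y = .data$neg_log10_p,
                                  colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(ns = "grey60", significant = "red3", panel = "blue3")) +
    ggplot2::labs(x = "difference, log2 LFQ (A - C)",
                  y = "-log10 p-value", colour = NULL) +
    ggplot2::theme_minimal()
}
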