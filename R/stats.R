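# Longitudinal statistics: normality-gated paired comparisons and
# Spearman correlations on baseline values and on pre/post deltas.

#' Paired pre/post comparison with a normality gate
#'
#' Shapiro-Wilk is applied to the paired differences; when they are
#' compatible with normality (p > `gate_alpha`) a paired t-test is used,
#' otherwise the Wilcoxon signed-rank test is substituted. The report
#' names the test that ran. Constant differences (zero variance) are a
#' degenerate case: reported as a no-difference result when all
#' differences are zero, and as a constant-shift result (no valid t
#' statistic) otherwise.
#'
#' @param pre,post numeric vectors of paired values (equal length,
#'   `n >= 3`).
#' @param alpha significance level for the comparison (default 0.05).
#' @param gate_alpha level of the Shapiro-Wilk normality gate.
#' @return list: `test` ("paired-t", "wilcoxon", "degenerate"),
#'   `statistic`, `p`, `n`, `significant`, `shapiro_p`, `mean_difference`.
#' @export
paired_compare <- function(pre, post, alpha = 0.05, gate_alpha = 0.05) {
  if (length(pre) != length(post)) stop("pre/post must be paired")
  keep <- stats::complete.cases(pre, post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(test = "degenerate", statistic = NA_real_,
                p = if (all(d == 0)) 1 else NA_real_, n = n,
                significant = FALSE, shapiro_p = NA_real_,
                mean_difference = mean(d)))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value > gate_alpha) {
    ht <- stats::t.test(post, pre, paired = TRUE)
    test <- "paired-t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
    test <- "wilcoxon"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       n = n, significant = ht$p.value < alpha, shapiro_p = sw$p.value,
       mean_difference = mean(d))
}

#' Welch's t-test for unpaired group contrasts
#'
#' Thin wrapper used for comparisons between independent groups (e.g.
#' patients vs controls), where pairing is unavailable.
#'
#' @param x,y numeric vectors.
#' @param alpha significance level.
#' @return list with `statistic`, `p`, `n`, `significant`.
#' @export
welch_compare <- function(x, y, alpha = 0.05) {
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n = c(length(x), length(y)), significant = ht$p.value < alpha)
}

#' Spearman rank correlation (baseline pooling)
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors, `n >= 4`.
#' @return list with `r`, `p`, `n`.
#' @export
spearman_baseline <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Spearman correlation of longitudinal deltas
#'
#' Computes per-subject changes `post - pre` for two metrics and
#' correlates the deltas. Subjects are matched by id across the two
#' tables; subjects missing either timepoint or metric are dropped.
#'
#' @param pre_table,post_table [metrics_table()] data.frames for the two
#'   timepoints.
#' @param metric_x,metric_y metric selectors: a list with `metric` and
#'   optionally `branch`, `window`, `statistic`, or a metric-name string.
#' @return list with `r`, `p`, `n`.
#' @export
spearman_delta <- function(pre_table, post_table, metric_x, metric_y) {
  get_vals <- function(tab, sel) {
    if (is.character(sel)) sel <- list(metric = sel)
    m <- tab$metric == sel$metric
    for (f in c("branch", "window", "statistic"))
      if (!is.null(sel[[f]])) m <- m & tab[[f]] == sel[[f]]
    sub <- tab[m, ]
    if (anyDuplicated(sub$subject))
      stop("metric selector is ambiguous: add branch/window/statistic")
    stats::setNames(sub$value, sub$subject)
  }
  dx <- delta_by_subject(get_vals(pre_table, metric_x),
                         get_vals(post_table, metric_x))
  dy <- delta_by_subject(get_vals(pre_table, metric_y),
                         get_vals(post_table, metric_y))
  ids <- intersect(names(dx), names(dy))
  if (length(ids) < 4)
    stop("need at least 4 matched subjects, got ", length(ids))
  spearman_baseline(dx[ids], dy[ids])
}

delta_by_subject <- function(pre, post) {
  ids <- intersect(names(pre), names(post))
  stats::setNames(post[ids] - pre[ids], ids)
}
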