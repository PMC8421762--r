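#' Area under the ROC curve by pair counting
#'
#' Computes `AUC = P(score_pos > score_neg) + 0.5 * P(tie)` via the
#' Mann-Whitney rank identity, i.e. the probability that a randomly chosen
#' positive subject scores above a randomly chosen negative one.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Binary labels (1 = positive/ASD).
#' @return The AUC, a single number in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.6, 0.7, 0.2), c(1, 1, 0, 0))  # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to compute an AUC")
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion counts and derived rates
#'
#' @param predicted Binary predictions (1 = positive).
#' @param labels Binary reference labels (1 = positive/ASD).
#' @return A one-row tibble with counts `tp`, `fn`, `tn`, `fp` and rates
#'   `sensitivity` (ASD detection), `specificity`, `accuracy` and
#'   `balanced_accuracy` (mean of sensitivity and specificity).
#' @export
confusion_metrics <- function(predicted, labels) {
  predicted <- as.integer(predicted)
  labels <- as.integer(labels)
  if (length(predicted) != length(labels)) abort("length mismatch")
  if (length(labels) == 0L) abort("empty input")
  tp <- sum(predicted == 1L & labels == 1L)
  fn <- sum(predicted == 0L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  fp <- sum(predicted == 1L & labels == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / length(labels),
         balanced_accuracy = (sens + spec) / 2)
}

#' Two-sample t-test and Cohen's d from summary statistics
#'
#' Recomputes group comparisons from published `N`, mean and SD alone, the
#' way cohort-description tables are audited. The default is the pooled
#' (Student) t; Welch's unequal-variance t is available. The sign
#' convention lists the ASD group first, so `t` is negative when the ASD
#' mean is higher. Cohen's d always uses the pooled SD.
#'
#' All arguments are vectorized, so a whole summary table can be tested in
#' one call.
#'
#' @param n1,m1,s1 Size, mean and SD of the first (ASD) group.
#' @param n2,m2,s2 Size, mean and SD of the second (non-ASD) group.
#' @param welch If `TRUE`, use Welch's t with Satterthwaite df.
#' @return A tibble with columns `t`, `df`, `p` (two-sided), `d` (Cohen's
#'   d, non-negative) and `pooled_sd`.
#' @export
#' @examples
#' pooled_t_from_summary(547, 9.76, 4.06, 802, 3.14, 3.49)
pooled_t_from_summary <- function(n1, m1, s1, n2, m2, s2, welch = FALSE) {
  if (any(n1 < 2) || any(n2 < 2)) abort("each group needs n >= 2")
  if (any(s1 < 0) || any(s2 < 0)) abort("standard deviations must be >= 0")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (welch) {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    se <- sp * sqrt(1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  t <- (m2 - m1) / se
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df), d = abs(m1 - m2) / sp,
         pooled_sd = sp)
}

#' Group-comparison summary for one variable of a cohort table
#'
#' Convenience wrapper producing one row of a sample-characteristics table:
#' per-class `n`, mean and SD of a numeric variable, followed by the
#' summary-statistics t-test of [pooled_t_from_summary()].
#'
#' @param data A data frame.
#' @param value Name of the numeric column to compare.
#' @param group Name of the binary grouping column (1 = ASD), default
#'   `"label"`.
#' @inheritParams pooled_t_from_summary
#' @return A one-row tibble: `n1`, `m1`, `s1`, `n2`, `m2`, `s2`, `t`, `df`,
#'   `p`, `d`.
#' @export
group_summary <- function(data, value, group = "label", welch = FALSE) {
  v <- data[[value]]
  g <- as.integer(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  stat <- function(cl) c(n = sum(g == cl), m = mean(v[g == cl]),
                         s = stats::sd(v[g == cl]))
  a <- stat(1L); b <- stat(0L)
  res <- pooled_t_from_summary(a[["n"]], a[["m"]], a[["s"]],
                               b[["n"]], b[["m"]], b[["s"]], welch = welch)
  tibble(variable = value, n1 = a[["n"]], m1 = a[["m"]], s1 = a[["s"]],
         n2 = b[["n"]], m2 = b[["m"]], s2 = b[["s"]],
         t = res$t, df = res$df, p = res$p, d = res$d)
}
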