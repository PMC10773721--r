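# Evaluation: confusion-derived metrics, rank AUC, printed-precision
# relative differences, and Welch/Games-Howell comparisons across repeated
# runs.

#' Confusion counts at a decision threshold
#'
#' @param labels Binary labels.
#' @param probs Predicted positive-class probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs))
  if (!all(labels %in% c(0, 1))) stop_injurisk("labels must be binary 0/1")
  pred <- as.integer(probs >= threshold)
  list(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

#' Rank-based ROC AUC
#'
#' The probability that a random positive outranks a random negative
#' (Mann-Whitney statistic with mid-rank tie handling); identical to the
#' trapezoidal area under the ROC curve.
#'
#' @param labels Binary labels (both classes must be present).
#' @param scores Predicted scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_injurisk("AUC undefined: one class absent")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-derived metric set
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, their
#' geometric mean, and (when scores are supplied) the rank AUC.
#'
#' @param counts Confusion counts from [confusion()].
#' @param labels,probs Optional; needed for AUC.
#' @return A `metric_set` list with `auc`, `sensitivity`, `specificity`,
#'   `gmean`.
#' @export
metric_set <- function(counts, labels = NULL, probs = NULL) {
  sens <- with(counts, TP / (TP + FN))
  spec <- with(counts, TN / (TN + FP))
  auc <- if (!is.null(labels)) auc_rank(labels, probs) else NA_real_
  structure(list(auc = auc, sensitivity = sens, specificity = spec,
                 gmean = sqrt(sens * spec)),
            class = "metric_set")
}

#' Evaluate predictions in one call
#' @inheritParams confusion
#' @return A `metric_set`.
#' @export
classification_metrics <- function(labels, probs, threshold = 0.5) {
  metric_set(confusion(labels, probs, threshold), labels, probs)
}

#' Geometric mean of sensitivity and specificity
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return `sqrt(sensitivity * specificity)`.
#' @export
gmean <- function(sensitivity, specificity) sqrt(sensitivity * specificity)

#' Relative difference between two metric values
#'
#' Percent improvement of `a` over the reference `b`,
#' `100 (a - b) / b`, with the companion signed mean difference
#' `MD = b - a` (reference minus comparator).
#'
#' @param a Metric value.
#' @param b Reference value (non-zero).
#' @return List with `percent` and `md`.
#' @export
relative_difference <- function(a, b) {
  if (b == 0) stop_injurisk("reference metric is zero")
  list(percent = 100 * (a - b) / b, md = b - a)
}

#' Welch's analysis of variance
#'
#' Heteroscedastic one-way ANOVA (no equal-variance assumption), as
#' implemented by [stats::oneway.test()].
#'
#' @param groups A named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values and positive variance).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(y ~ g, var.equal = FALSE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = unname(ft$p.value))
}

check_groups <- function(groups) {
  if (length(groups) < 2) stop_injurisk("need >= 2 groups")
  for (i in seq_along(groups)) {
    if (length(groups[[i]]) < 2) stop_injurisk("group %d has < 2 values", i)
    if (stats::var(groups[[i]]) <= 0) stop_injurisk("group %d has zero variance", i)
  }
}

#' Games-Howell post-hoc comparisons
#'
#' Pairwise comparisons for unequal variances and sample sizes: Welch-type
#' standard errors and degrees of freedom with studentized-range p-values.
#' Reports the mean difference `MD = mean_i - mean_j` for each pair.
#'
#' @param groups A named list of numeric vectors.
#' @return Data frame with one row per pair: `group1`, `group2`, `md`, `se`,
#'   `t`, `df`, `p`.
#' @export
games_howell <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    tval <- (m[i] - m[j]) / sqrt(se2)
    p <- stats::ptukey(abs(tval) * sqrt(2), k, df, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = nm[i], group2 = nm[j],
                                 md = m[i] - m[j], se = sqrt(se2),
                                 t = tval, df = df, p = p))
  }
  rownames(out) <- NULL
  out
}
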