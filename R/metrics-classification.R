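# Confusion-matrix statistics, ROC/AUC and McNemar's paired comparison.
# Positive class = malignant = 1 throughout.

#' Confusion counts from paired label vectors
#'
#' @param pred_labels,true_labels equal-length 0/1 vectors (1 = malignant).
#' @return a `confusion_counts` list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop_validation("prediction and truth vectors differ in length")
  }
  if (!all(pred_labels %in% c(0, 1)) || !all(true_labels %in% c(0, 1))) {
    stop_validation("labels must be 0 (benign) or 1 (malignant)")
  }
  structure(list(tp = sum(pred_labels == 1 & true_labels == 1),
                 fp = sum(pred_labels == 1 & true_labels == 0),
                 tn = sum(pred_labels == 0 & true_labels == 0),
                 fn = sum(pred_labels == 0 & true_labels == 1)),
            class = "confusion_counts")
}

#' Build confusion counts directly from the four cells
#' @param tp,fp,tn,fn nonnegative integers.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop_config("counts must be nonnegative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Headline metrics from confusion counts, as percentages
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1, each on the
#' 0-100 scale and unrounded (round only for presentation). A metric whose
#' denominator is zero is reported as `NA` (absent), never as 0.
#'
#' @param counts a `confusion_counts` object.
#' @return named list of percentages (`NA` where undefined).
#' @export
summary_metrics <- function(counts) {
  with(counts, {
    total <- tp + fp + tn + fn
    if (total == 0) stop_config("empty confusion table")
    pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    precision <- pct(tp, tp + fp)
    recall <- pct(tp, tp + fn)
    f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    list(accuracy = 100 * (tp + tn) / total,
         precision = precision,
         recall = recall,
         sensitivity = recall,
         specificity = pct(tn, tn + fp),
         f1 = f1)
  })
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (descending), grouping
#' tied scores into a single step, and integrates by the trapezoid rule --
#' which half-counts ties, so the AUC equals the Mann-Whitney pairwise
#' statistic.
#'
#' @param scores numeric malignancy scores.
#' @param true_labels 0/1 vector; both classes must be present.
#' @return a `roc_curve`: `thresholds` (descending, starting at `Inf`), `fpr`,
#'   `tpr` (each nondecreasing from 0 to 1) and `auc`.
#' @export
roc_auc <- function(scores, true_labels) {
  if (length(scores) != length(true_labels)) {
    stop_validation("scores and labels differ in length")
  }
  n_pos <- sum(true_labels == 1); n_neg <- sum(true_labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("ROC needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- true_labels[ord]
  group_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(y == 1)[group_last] / n_pos)
  fpr <- c(0, cumsum(y == 0)[group_last] / n_neg)
  thresholds <- c(Inf, s[group_last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds, AUC = %.4f\n", length(x$thresholds), x$auc))
  invisible(x)
}

#' McNemar's test on discordant counts
#'
#' `b` and `c` are the two discordant cells of the paired 2x2 table (model A
#' right / model B wrong, and vice versa). The asymptotic statistic is
#' `(b-c)^2/(b+c)` (continuity-corrected: `(|b-c|-1)^2/(b+c)`), with the
#' p-value from the chi-squared distribution with 1 df. Because the
#' asymptotic test is unreliable for few discordant pairs, the exact binomial
#' p-value (sign test on b successes out of b+c at rate 1/2) is the headline
#' `p` whenever `b + c < 25` (or when `exact = TRUE`).
#'
#' @param b,c nonnegative discordant counts with `b + c > 0`.
#' @param corrected apply the continuity correction to the chi-squared
#'   statistic.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact binomial
#'   p-value; default `NULL` chooses exact iff `b + c < 25`.
#' @return list with `chi2`, `p_chi2`, `p_exact` (NA when not computed), `p`
#'   (the headline p-value) and `method`.
#' @export
mcnemar <- function(b, c, corrected = FALSE, exact = NULL) {
  if (b < 0 || c < 0) stop_config("discordant counts must be nonnegative")
  n <- b + c
  if (n == 0) stop_config("no discordant pairs: McNemar's test is undefined")
  chi2 <- if (corrected) (abs(b - c) - 1)^2 / n else (b - c)^2 / n
  p_chi2 <- pchisq(chi2, df = 1, lower.tail = FALSE)
  use_exact <- if (is.null(exact)) n < 25 else isTRUE(exact)
  p_exact <- if (use_exact) min(1, 2 * pbinom(min(b, c), n, 0.5)) else NA_real_
  list(chi2 = chi2, p_chi2 = p_chi2, p_exact = p_exact,
       p = if (use_exact) p_exact else p_chi2,
       method = if (use_exact) "exact binomial" else
         if (corrected) "chi-squared (corrected)" else "chi-squared")
}
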