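#' Confusion-matrix classification metrics
#'
#' Counts the 2x2 table of 0/1 `predictions` against 0/1 `truths` and
#' reports sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/n, PPV TP/(TP+FP) and NPV TN/(TN+FN), all in percent. A ratio
#' with a zero denominator is reported as `NA` (never coerced to 0), and
#' stays `NA` through aggregation.
#'
#' @param predictions integer 0/1 calls.
#' @param truths integer 0/1 true classes, same length.
#' @param scores optional continuous scores for [roc_auc()]; when supplied
#'   the report carries `auc`.
#' @return A `diagnostics_report`: TP/FP/TN/FN counts, the five percentages,
#'   `n`, and `auc` (or `NA`).
#' @export
confusion_metrics <- function(predictions, truths, scores = NULL) {
  if (length(predictions) != length(truths)) stop_nbc("predictions and truths differ in length")
  if (!length(truths)) stop_nbc("empty evaluation set")
  predictions <- as.integer(predictions); truths <- as.integer(truths)
  tp <- sum(predictions == 1 & truths == 1)
  fp <- sum(predictions == 1 & truths == 0)
  tn <- sum(predictions == 0 & truths == 0)
  fn <- sum(predictions == 0 & truths == 1)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  auc <- if (!is.null(scores) && length(unique(truths)) == 2) roc_auc(scores, truths) else NA_real_
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, n = length(truths),
                 sensitivity = pct(tp, tp + fn),
                 specificity = pct(tn, tn + fp),
                 accuracy = pct(tp + tn, length(truths)),
                 ppv = pct(tp, tp + fp),
                 npv = pct(tn, tn + fn),
                 auc = auc),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("n=%d TP=%d FP=%d TN=%d FN=%d | sens %.1f%% spec %.1f%% acc %.1f%% PPV %.1f%% NPV %.1f%%%s\n",
              x$n, x$TP, x$FP, x$TN, x$FN, x$sensitivity, x$specificity,
              x$accuracy, x$ppv, x$npv,
              if (is.na(x$auc)) "" else sprintf(" AUC %.3f", x$auc)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive scores
#' above a random negative, with half credit for ties (the average-rank
#' formulation), so it is invariant to any strictly increasing transform of
#' the scores.
#'
#' @param scores continuous risk scores.
#' @param truths 0/1 true classes; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truths) {
  if (length(scores) != length(truths)) stop_nbc("scores and truths differ in length")
  truths <- as.integer(truths)
  n1 <- sum(truths == 1); n0 <- sum(truths == 0)
  if (n1 == 0 || n0 == 0) stop_nbc("ROC AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truths == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate diagnostics over repeated splits
#'
#' Mean and sample standard deviation (n - 1 denominator) of each metric
#' across split-level reports; `NA` metrics (undefined ratios) are excluded
#' pairwise.
#'
#' @param reports list of `diagnostics_report`s (at least 2).
#' @return An `aggregate_report`: data.frame with one row per metric and
#'   columns `mean` and `sd`.
#' @export
aggregate_splits <- function(reports) {
  if (length(reports) < 2) stop_nbc("need at least 2 reports to aggregate")
  metrics <- c("sensitivity", "specificity", "accuracy", "ppv", "npv", "auc")
  m <- sapply(metrics, function(k) vapply(reports, function(r) r[[k]] %||% NA_real_, numeric(1)))
  out <- data.frame(metric = metrics,
                    mean = apply(m, 2, mean, na.rm = TRUE),
                    sd = apply(m, 2, stats::sd, na.rm = TRUE),
                    row.names = NULL)
  structure(out, class = c("aggregate_report", "data.frame"))
}
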