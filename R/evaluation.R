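# Screening metrics: confusion counts, accuracy/sensitivity/specificity,
# ROC curve and AUC (positive class = referable, grade >= 2).

#' Confusion counts at a probability threshold
#'
#' A score `>= threshold` is called positive (referable); ties at the
#' threshold therefore count positive.
#'
#' @param labels Binary vector (0/1 or logical), 1 = referable.
#' @param probabilities Numeric scores of the same length.
#' @param threshold Operating point, default 0.5.
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities))
    stop("labels and probabilities must have equal length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  pred <- probabilities >= threshold
  structure(list(
    TP = sum(pred & labels == 1L),
    FP = sum(pred & labels == 0L),
    TN = sum(!pred & labels == 0L),
    FN = sum(!pred & labels == 1L),
    threshold = threshold), class = "confusion_counts")
}

#' Screening metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)`, reported as percentages. An empty class raises an error
#' rather than returning a silent `NaN`.
#'
#' @param counts A `confusion_counts` object.
#' @return Object of class `eval_report` with fields `accuracy`,
#'   `sensitivity`, `specificity` (percent), and `counts`.
#' @export
screening_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0L) stop("no records to evaluate")
  if (counts$TP + counts$FN == 0L)
    stop("sensitivity undefined: no positive (referable) records")
  if (counts$TN + counts$FP == 0L)
    stop("specificity undefined: no negative records")
  structure(list(
    accuracy = 100 * (counts$TP + counts$TN) / total,
    sensitivity = 100 * counts$TP / (counts$TP + counts$FN),
    specificity = 100 * counts$TN / (counts$TN + counts$FP),
    auc = NA_real_,
    threshold = counts$threshold,
    counts = counts), class = "eval_report")
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds, returns `(FPR, TPR)` points and the area
#' under the curve by trapezoidal integration. Tied scores form a single
#' diagonal segment, so the area equals the Mann-Whitney pairwise
#' concordance with ties counted 1/2 (midrank convention).
#'
#' @param labels Binary vector, 1 = referable.
#' @param probabilities Numeric scores.
#' @return List with `auc` (fraction in `[0, 1]`) and `curve`, a data frame
#'   of `threshold`, `fpr`, `tpr` points.
#' @export
roc_auc <- function(labels, probabilities) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities))
    stop("labels and probabilities must have equal length")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present")
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probabilities[ord]
  # indices where a score block ends (last occurrence of each unique score)
  block_end <- which(sc != c(sc[-1], NA) | seq_along(sc) == length(sc))
  tpr <- c(0, cumsum(lab == 1L)[block_end] / n_pos)
  fpr <- c(0, cumsum(lab == 0L)[block_end] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, sc[block_end]),
                          fpr = fpr, tpr = tpr))
}

#' Full evaluation report
#'
#' Convenience wrapper: confusion at `threshold`, percentage metrics, and
#' AUC, bundled as an `eval_report`.
#'
#' @inheritParams confusion_counts
#' @return An `eval_report` with `auc` filled in.
#' @export
evaluate_predictions <- function(labels, probabilities, threshold = 0.5) {
  rep <- screening_metrics(confusion_counts(labels, probabilities, threshold))
  rep$auc <- roc_auc(labels, probabilities)$auc
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Screening evaluation (threshold %.2f, n = %d)\n", x$threshold,
              x$counts$TP + x$counts$FP + x$counts$TN + x$counts$FN))
  cat(sprintf("  Accuracy    %6.2f %%\n", x$accuracy))
  cat(sprintf("  Sensitivity %6.2f %%\n", x$sensitivity))
  cat(sprintf("  Specificity %6.2f %%\n", x$specificity))
  if (!is.na(x$auc)) cat(sprintf("  AUC         %6.4f\n", x$auc))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              x$counts$TP, x$counts$FP, x$counts$TN, x$counts$FN))
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, auc = report$auc,
    threshold = report$threshold,
    counts = report$counts[c("TP", "FP", "TN", "FN")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
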