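#' Confusion counts for binary CAD diagnosis
#'
#' CAD is the positive class.
#'
#' @param predictions Predicted labels (`"CAD"` / `"non-CAD"`).
#' @param labels True labels, same length.
#' @return Object of class `"confusion_counts"`: list with `TP`, `TN`,
#'   `FP`, `FN`, `N`.
#' @export
confusion <- function(predictions, labels) {
  predictions <- as.character(predictions); labels <- as.character(labels)
  if (length(predictions) == 0) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  tp <- sum(predictions == "CAD" & labels == "CAD")
  tn <- sum(predictions == "non-CAD" & labels == "non-CAD")
  fp <- sum(predictions == "CAD" & labels == "non-CAD")
  fn <- sum(predictions == "non-CAD" & labels == "CAD")
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, N = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  (N = %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$N))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from confusion counts
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, and negative predictive value
#' `TN/(TN+FN)`.  A zero denominator yields `NA` (an explicit undefined
#' marker), never an error.
#'
#' @param c A [confusion()] result.
#' @return Object of class `"metric_report"`: named list of the five
#'   metrics as fractions in `[0, 1]`.
#' @export
tet_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$N < 1) stop("metrics require at least one sample")
  structure(list(accuracy = safe_ratio(c$TP + c$TN, c$N),
                 sensitivity = safe_ratio(c$TP, c$TP + c$FN),
                 specificity = safe_ratio(c$TN, c$TN + c$FP),
                 precision = safe_ratio(c$TP, c$TP + c$FP),
                 npv = safe_ratio(c$TN, c$TN + c$FN)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.2f%%", 100 * x[[nm]])))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct scores, collecting
#' `(FPR, TPR)` points, and integrates the curve with the trapezoidal rule.
#' With distinct scores this equals the concordant-pair (Mann-Whitney)
#' statistic; ties contribute half weight through the trapezoids.
#'
#' @param scores Numeric CAD probabilities or scores (higher = more CAD).
#' @param labels True labels (`"CAD"` positive).
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "CAD"
  if (!any(pos) || all(pos))
    stop("AUC undefined: need at least one positive and one negative label")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}
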