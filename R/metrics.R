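# Confusion matrix and the imbalance-aware evaluation suite. Overall accuracy
# is dominated by the majority class, so per-class accuracies, their geometric
# mean (G-mean) and the positive-class F-measure carry the signal here.

#' Confusion matrix for a two-class problem
#'
#' The expert (true) label is the row, the classifier prediction the column;
#' `+1` is the positive (nodule/minority) class.
#'
#' @param y_true,y_pred equal-length vectors of labels in `{+1, -1}`.
#' @return an object of class `confusion_matrix`: list with integer `TP`,
#'   `FN`, `FP`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort_rusmote("y_true and y_pred must have equal length",
                  "rusmote_shape_mismatch")
  }
  if (!all(y_true %in% c(-1, 1)) || !all(y_pred %in% c(-1, 1))) {
    abort_rusmote("labels must be +1 or -1", "rusmote_bad_label")
  }
  confusion_matrix(TP = sum(y_true == 1 & y_pred == 1),
                   FN = sum(y_true == 1 & y_pred == -1),
                   FP = sum(y_true == -1 & y_pred == 1),
                   TN = sum(y_true == -1 & y_pred == -1))
}

#' @rdname confusion
#' @param TP,FN,FP,TN nonnegative counts.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_rusmote("confusion counts must be nonnegative integers",
                  "rusmote_bad_counts")
  }
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("true +1", "true -1"),
                              c("pred +1", "pred -1")))
  print(m)
  invisible(x)
}

#' Evaluate a confusion matrix
#'
#' Computes the full metric suite:
#' `accuracy = (TP + TN) / total`; `tpr = acc_plus = recall = TP / (TP + FN)`;
#' `fpr = FP / (FP + TN)`; `acc_minus = TN / (TN + FP)`;
#' `g_mean = sqrt(acc_plus * acc_minus)`; `precision = TP / (TP + FP)`;
#' `f_measure = 2 P R / (P + R)`.
#'
#' A zero denominator makes the affected metric `NA` with a classed warning
#' rather than silently 0; `f_measure` is 0 when `TP = 0` but some positive
#' exists on either side.
#'
#' @param cm a [confusion_matrix()] with at least one sample.
#' @return an object of class `metric_report`: named list of the nine metrics.
#' @export
evaluate <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    abort_rusmote("cm must be a confusion_matrix", "rusmote_bad_counts")
  }
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0) {
    abort_rusmote("empty confusion matrix", "rusmote_bad_counts")
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn_rusmote(sprintf("%s is undefined (zero denominator)", what),
                   "rusmote_undefined_metric")
      return(NA_real_)
    }
    num / den
  }
  acc_plus <- safe_div(cm$TP, cm$TP + cm$FN, "positive-class accuracy")
  acc_minus <- safe_div(cm$TN, cm$TN + cm$FP, "negative-class accuracy")
  precision <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  recall <- acc_plus
  f_measure <- if (is.na(recall)) {
    NA_real_
  } else if (cm$TP == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    accuracy = (cm$TP + cm$TN) / total,
    tpr = acc_plus,
    fpr = if (is.na(acc_minus)) NA_real_ else 1 - acc_minus,
    acc_plus = acc_plus,
    acc_minus = acc_minus,
    g_mean = sqrt(acc_plus * acc_minus),
    precision = precision,
    recall = recall,
    f_measure = f_measure
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%-10s %s", names(v), formatC(v, digits = digits,
                                                  format = "f")),
            collapse = "\n"), "\n")
  invisible(x)
}
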