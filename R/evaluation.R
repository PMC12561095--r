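#' Confusion matrices and classification metrics
#'
#' Evaluation follows the usual multiclass one-vs-rest decomposition:
#' per-class true positives, false positives and false negatives from the
#' confusion matrix (rows = actual, columns = predicted), per-class
#' precision, recall and F1, and both weighted (class-support weights) and
#' macro (unweighted mean) aggregates. Weighted recall is algebraically
#' identical to overall accuracy in the multiclass setting, a property the
#' tests assert on every report.
#'
#' @name evaluation
NULL

#' Build a confusion matrix
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Optional class inventory fixing row/column order;
#'   defaults to the sorted union of the observed labels.
#' @return An integer matrix of class `confusion_matrix`, rows = actual,
#'   columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  if (length(actual) != length(predicted)) {
    fs_abort("actual and predicted must have the same length",
             "fs_eval_error")
  }
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  if (!all(c(actual, predicted) %in% classes)) {
    fs_abort("labels outside the declared class inventory", "fs_eval_error")
  }
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  out <- matrix(as.integer(cm), nrow = length(classes),
                dimnames = list(actual = classes, predicted = classes))
  structure(out, class = c("confusion_matrix", class(out)))
}

#' Metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Per class, precision is
#' `TP / (TP + FP)`, recall is `TP / (TP + FN)` and F1 their harmonic
#' mean; a zero denominator yields 0 with a warning. Weighted aggregates
#' use per-class actual counts as weights, macro aggregates are unweighted
#' means over classes.
#'
#' @param cm A [confusion_matrix()].
#' @return An `eval_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1` (weighted), their `macro_*` counterparts, a `per_class` data
#'   frame (support, precision, recall, f1) and the `confusion` matrix.
#' @export
metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix") || sum(cm) == 0) {
    fs_abort("metrics require a non-empty confusion matrix", "fs_eval_error")
  }
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0)) {
      warning("zero denominator in a per-class metric; reporting 0",
              call. = FALSE)
    }
    out
  }
  precision_c <- safe_div(tp, tp + fp)
  recall_c <- safe_div(tp, tp + fn)
  f1_c <- ifelse(precision_c + recall_c > 0,
                 2 * precision_c * recall_c / (precision_c + recall_c), 0)
  support <- rowSums(cm)
  w <- support / total
  per_class <- data.frame(class = rownames(cm), support = as.integer(support),
                          precision = unname(precision_c),
                          recall = unname(recall_c), f1 = unname(f1_c),
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    accuracy = sum(tp) / total,
    precision = sum(w * precision_c),
    recall = sum(w * recall_c),
    f1 = sum(w * f1_c),
    macro_precision = mean(precision_c),
    macro_recall = mean(recall_c),
    macro_f1 = mean(f1_c),
    per_class = per_class,
    confusion = cm
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: n=%d  accuracy=%.4f  precision=%.4f  recall=%.4f  f1=%.4f>\n",
    sum(x$confusion), x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
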