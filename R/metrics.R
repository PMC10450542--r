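#' Confusion-derived evaluation metrics
#'
#' Precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), F1 = harmonic mean of precision and sensitivity, accuracy,
#' and balanced accuracy = (sensitivity + specificity)/2. Zero denominators
#' give 0 by convention. The positive class is "depressed".
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @param auc Optional area under the ROC curve to carry along.
#' @return An `eval_report` list.
#' @export
metrics <- function(tp, fp, tn, fn, auc = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  safe_div <- function(a, b) if (b > 0) a / b else 0
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else 0
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, sensitivity = sensitivity,
                 specificity = specificity, f1 = f1,
                 accuracy = (tp + tn) / (tp + fp + tn + fn),
                 balanced_accuracy = (sensitivity + specificity) / 2,
                 auc = auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("eval_report: precision %.3f, sensitivity %.3f, ",
                     "specificity %.3f, F1 %.3f, accuracy %.3f, ",
                     "balanced accuracy %.3f, AUC %s\n"),
              x$precision, x$sensitivity, x$specificity, x$f1, x$accuracy,
              x$balanced_accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

eval_from_predictions <- function(truth01, pred01, score = NULL) {
  tp <- sum(truth01 == 1 & pred01 == 1)
  fp <- sum(truth01 == 0 & pred01 == 1)
  tn <- sum(truth01 == 0 & pred01 == 0)
  fn <- sum(truth01 == 1 & pred01 == 0)
  auc <- if (is.null(score)) NA_real_ else roc_auc(truth01, score)
  metrics(tp, fp, tn, fn, auc = auc)
}

#' Rank-based AUC (Mann-Whitney)
#'
#' @param truth01 Binary ground truth.
#' @param score Classifier scores (class-1 probabilities).
#' @return AUC in `[0,1]`; `NA` when one class is absent.
#' @export
roc_auc <- function(truth01, score) {
  n1 <- sum(truth01 == 1); n0 <- sum(truth01 == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
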