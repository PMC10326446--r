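#' Pair-based sensitivity, specificity and F1 of a predicted labelling
#'
#' Evaluation over all `choose(n, 2)` unordered cell pairs: a pair is
#' *related* when the two cells share a true type and *predicted related*
#' when they share a predicted label (`"unclassified"` counts as a label of
#' its own). Then TP = related pairs predicted related, FP = unrelated
#' pairs predicted related, TN = unrelated predicted unrelated, FN =
#' related predicted unrelated, and sensitivity = TP/(TP+FN), specificity
#' = TN/(TN+FP), F1 = 2TP/(2TP+FP+FN). Computed from the truth-by-
#' prediction contingency table in O(n + L^2).
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels, same cells, same
#'   order.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `f1`.
#' @export
pair_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted cover different numbers of cells", call. = FALSE)
  }
  n <- length(truth)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  tab <- table(truth, predicted)
  ch2 <- function(k) sum(k * (k - 1) / 2)
  tp <- ch2(as.vector(tab))
  same_pred <- ch2(colSums(tab))
  same_truth <- ch2(rowSums(tab))
  total <- n * (n - 1) / 2
  fp <- same_pred - tp
  fn <- same_truth - tp
  tn <- total - tp - fp - fn
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    f1 = 2 * tp / (2 * tp + fp + fn)
  )
}
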