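## Confusion-count performance indicators.

#' Classifier performance from confusion counts
#'
#' Matthews correlation coefficient, sensitivity (recall), specificity and
#' precision from TP/FP/TN/FN counts.  The MCC is defined as
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' and set to 0 whenever any factor of the denominator vanishes (the
#' random-classification value); undefined 0/0 ratios are likewise
#' reported as 0.
#'
#' @param counts named numeric vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return list with `mcc`, `sensitivity`, `specificity`, `precision`.
#' @examples
#' confusion_metrics(c(TP = 2, FP = 1, TN = 2, FN = 1))$mcc  # 1/3
#' @export
confusion_metrics <- function(counts) {
  tp <- as.double(counts[["TP"]]); fp <- as.double(counts[["FP"]])
  tn <- as.double(counts[["TN"]]); fn <- as.double(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  ratio <- function(num, den) if (den == 0) 0 else num / den
  list(mcc = mcc,
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp))
}

.count_confusion <- function(truth, predicted) {
  c(TP = sum(truth > 0 & predicted > 0),
    FP = sum(truth <= 0 & predicted > 0),
    TN = sum(truth <= 0 & predicted <= 0),
    FN = sum(truth > 0 & predicted <= 0))
}
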