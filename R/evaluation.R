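# Imbalance-aware classification metrics.
#
# With outcome prevalence near 1%, raw accuracy is useless (the all-negative
# classifier scores 99%). The pipeline therefore evaluates every model with
# AUC and the balanced error rate BER = 1 - 0.5 * (TPR + TNR), both of which
# weight the two classes equally regardless of prevalence.

#' Area under the ROC curve
#'
#' Computed exactly via the midrank (Mann-Whitney) identity: the AUC equals
#' the proportion of (positive, negative) score pairs in which the positive
#' case receives the higher score, ties counted 1/2. No trapezoid
#' approximation is involved, so the value is exact for any finite sample.
#'
#' @param scores Numeric vector of classifier scores (any monotone scale).
#' @param labels Binary labels (0/1, logical, or two-level factor) aligned
#'   with `scores`; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)) # 3 of 4 pairs concordant
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  assert_both_classes(labels, "auc()")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion rates at a hard threshold
#'
#' @param scores,labels As in [auc()].
#' @param threshold Scores `>= threshold` are called positive.
#' @return List with `tpr`, `tnr`, and the `threshold` used.
#' @export
confusion <- function(scores, labels, threshold = 0.5) {
  labels <- as_binary_labels(labels)
  stopifnot(is.numeric(scores), length(scores) == length(labels),
            is.numeric(threshold), length(threshold) == 1L)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  assert_both_classes(labels, "confusion()")
  list(
    tpr = mean(scores[labels == 1L] >= threshold),
    tnr = mean(scores[labels == 0L] < threshold),
    threshold = threshold
  )
}

#' Balanced error rate
#'
#' `1 - 0.5 * (tpr + tnr)`: the average of the class-specific error rates,
#' insensitive to prevalence. A perfect classifier scores 0; the trivial
#' all-one-class classifier scores 0.5.
#'
#' @param tpr,tnr True positive / true negative rates in `[0, 1]`.
#' @return BER in `[0, 1]`.
#' @export
ber <- function(tpr, tnr) {
  stopifnot(is.numeric(tpr), is.numeric(tnr))
  if (any(tpr < 0 | tpr > 1) || any(tnr < 0 | tnr > 1)) {
    stop("tpr and tnr must lie in [0, 1]")
  }
  1 - 0.5 * (tpr + tnr)
}

#' All evaluation metrics at once
#'
#' @inheritParams confusion
#' @return List with `auc`, `tpr`, `tnr`, `ber`, `threshold`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  cm <- confusion(scores, labels, threshold)
  list(
    auc = auc(scores, labels),
    tpr = cm$tpr,
    tnr = cm$tnr,
    ber = ber(cm$tpr, cm$tnr),
    threshold = threshold
  )
}
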