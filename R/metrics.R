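# Threshold-free classification metrics, computed from first principles:
# trapezoidal ROC integration and step-function precision-recall
# integration. Tied scores are grouped so the ROC area equals the
# Mann-Whitney U statistic / (n_pos * n_neg) exactly.

#' ROC curve points
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels 0/1 (or logical) true labels.
#' @return data.frame with columns fpr, tpr, one row per distinct score
#'   cutoff plus the (0, 0) origin.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(as.logical(as.integer(labels)))
  stopifnot(length(scores) == length(labels),
            any(labels == 1), any(labels == 0))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: one ROC vertex per distinct cutoff
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(fpr = c(0, fp / sum(labels == 0)),
             tpr = c(0, tp / sum(labels == 1)))
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Equals the Mann-Whitney U statistic divided by n_pos * n_neg (ties
#' counted 1/2), a property the test suite checks against brute-force
#' pair counting.
#'
#' @inheritParams rocCurve
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  curve <- rocCurve(scores, labels)
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

#' Area under the precision-recall curve by step integration
#'
#' Sums precision * recall-increment over distinct score cutoffs in
#' decreasing score order (the step-function estimator, equal to average
#' precision when scores are untied).
#'
#' @inheritParams rocCurve
#' @return AUPR in \[0, 1\].
#' @export
prAupr <- function(scores, labels) {
  labels <- as.integer(as.logical(as.integer(labels)))
  stopifnot(length(scores) == length(labels), any(labels == 1))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]
  n <- cumsum(rep(1, length(y)))[last]
  precision <- tp / n
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}
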