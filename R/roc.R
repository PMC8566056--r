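#' ROC curve by threshold sweep
#'
#' Standard ROC for a continuous score against a binary label, positive
#' class = label 1, decision rule "score >= threshold is positive". The
#' curve runs from (0, 0) (threshold above all scores) to (1, 1) and is
#' reported without any orientation flipping, so scores that are *lower*
#' in the positive class yield a curve below the diagonal and an AUC below
#' 0.5.
#'
#' @param values Numeric scores, one per subject.
#' @param labels Binary labels (0/1), same length; both classes required.
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`; the first
#'   row is (0, 0) with threshold `Inf`.
#' @export
roc_curve <- function(values, labels) {
  ok <- .check_two_class(values, labels)
  values <- ok$values; labels <- ok$labels
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(values >= t & labels == 1L) / np, 0)
  fpr <- vapply(thr, function(t) sum(values >= t & labels == 0L) / nn, 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Computed directly as the Mann-Whitney probability that a positive-class
#' score exceeds a negative-class score, ties counting one half:
#' `(#(pos > neg) + 0.5 * #(pos == neg)) / (n_pos * n_neg)`. Identical to
#' the trapezoidal area under [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(3, 4, 1, 2), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(values, labels) {
  ok <- .check_two_class(values, labels)
  values <- ok$values; labels <- ok$labels
  pos <- values[labels == 1L]; neg <- values[labels == 0L]
  r <- rank(c(pos, neg))  # midranks handle ties as 0.5
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# drop NA scores, validate binary labels with both classes present
.check_two_class <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("'labels' must be 0/1", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present (after dropping undefined values)",
         call. = FALSE)
  list(values = values, labels = labels)
}
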