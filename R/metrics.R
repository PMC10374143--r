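# Threshold-free evaluation metrics. The minority class is always the
# positive class.

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision: rows are sorted by descending
#' score, tied scores are grouped into a single threshold, and
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over the distinct thresholds. This
#' convention avoids the optimistic bias of interpolated PR area. With
#' all scores identical the value collapses to the positive prevalence.
#'
#' @param scores Continuous classifier scores (higher = more positive).
#' @param labels Binary labels; 1 (or the rarer class) is positive.
#' @return AUPRC in \[0, 1\].
#' @export
#' @examples
#' auprc(c(4, 3, 2, 1), c(1, 0, 1, 0)) # 0.8333
auprc <- function(scores, labels) {
  pr <- score_curve(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Area under the ROC curve
#'
#' Trapezoidal ROC area, computed as the tie-corrected rank-sum
#' (Mann-Whitney) statistic.
#'
#' @inheritParams auprc
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- positive_indicator(scores, labels)
  n_pos <- sum(y)
  n_neg <- length(y) - n_pos
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

positive_indicator <- function(scores, labels) {
  if (any(!is.finite(scores))) abort("scores must be finite")
  if (length(unique(labels)) < 2L) abort("both classes must be present in `labels`")
  as.numeric(labels == minority_label(labels))
}

# Precision/recall at each distinct descending score threshold.
score_curve <- function(scores, labels) {
  y <- positive_indicator(scores, labels)
  ord <- order(-scores)
  s <- scores[ord]
  y <- y[ord]
  cut <- which(diff(s) != 0)
  last <- c(cut, length(s))
  tp <- cumsum(y)[last]
  n_at <- last
  tibble(
    threshold = s[last],
    precision = tp / n_at,
    recall = tp / sum(y)
  )
}
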