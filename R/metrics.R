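#' Area under the ROC curve (rank statistic)
#'
#' Computed as the normalized Mann-Whitney U statistic with midrank tie
#' handling; equivalent to trapezoidal integration of the empirical ROC
#' curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return AUROC in [0, 1]; NA if a class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels); n0 <- length(labels) - n1
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise interpolation (average precision): the sum over positives,
#' in decreasing score order, of precision at each recall increment.
#' Avoids the optimistic bias of trapezoidal PR interpolation.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1]; NA if no positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels)
  if (n1 == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  ## tied scores form one threshold block sharing the block-end precision
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  block_end_prec <- prec[ends[findInterval(seq_along(s), ends,
                                           left.open = TRUE) + 1L]]
  sum(block_end_prec[y == 1]) / n1
}

#' F1 score at a fixed threshold
#' @inheritParams auroc
#' @param threshold decision threshold on the scores.
#' @return F1 in [0, 1]; NA when precision and recall are both 0.
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels > 0)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Cluster (subject-level) bootstrap confidence interval for AUROC
#'
#' Resamples subjects with replacement and recomputes the pooled AUROC,
#' respecting within-subject correlation of epochs.
#'
#' @inheritParams auroc
#' @param subjects subject id per score.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return Named vector `c(lo, hi, point)`.
#' @export
auroc_boot_ci <- function(scores, labels, subjects, n_boot = 1000,
                          conf = 0.95, seed = 1L) {
  set.seed(seed)
  ids <- unique(subjects)
  stats_ <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(lapply(take, function(id) which(subjects == id)))
    stats_[b] <- auroc(scores[idx], labels[idx])
  }
  stats_ <- stats_[is.finite(stats_)]
  qs <- stats::quantile(stats_, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  c(lo = qs[1], hi = qs[2], point = auroc(scores, labels))
}
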