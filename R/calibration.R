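#' Reliability table of predicted probabilities
#'
#' Bins predictions into `n_bins` equal-width bins `[i/n, (i+1)/n)`
#' (last bin closed at 1) and tabulates per-bin mean predicted
#' probability (confidence), empirical positive fraction (accuracy)
#' and count. Empty bins carry count 0 and NA accuracy.
#'
#' @param probs probabilities in [0, 1].
#' @param labels binary outcomes, same length.
#' @param n_bins number of bins.
#' @return data.frame of class `"reliability_table"` with columns
#'   bin_lo, bin_hi, confidence, accuracy, count.
#' @export
reliability <- function(probs, labels, n_bins = 10L) {
  if (length(probs) != length(labels))
    stop("probs and labels must have equal length")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  labels <- as.integer(labels > 0)
  bin <- pmin(floor(probs * n_bins), n_bins - 1L) + 1L
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) / n_bins,
                    bin_hi = seq_len(n_bins) / n_bins,
                    confidence = NA_real_, accuracy = NA_real_,
                    count = 0L)
  for (b in seq_len(n_bins)) {
    idx <- bin == b
    out$count[b] <- sum(idx)
    if (out$count[b] > 0) {
      out$confidence[b] <- mean(probs[idx])
      out$accuracy[b] <- mean(labels[idx])
    }
  }
  class(out) <- c("reliability_table", "data.frame")
  out
}

#' @export
plot.reliability_table <- function(x, ...) {
  occ <- x[x$count > 0, ]
  graphics::plot(occ$confidence, occ$accuracy, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "mean predicted probability",
                 ylab = "observed positive fraction",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Expected calibration error
#'
#' Count-weighted mean absolute gap between per-bin accuracy and
#' confidence: `sum_b (n_b / N) |acc_b - conf_b|`. Zero for perfectly
#' calibrated binned predictions; at most 1.
#'
#' @param table a [reliability()] table.
#' @return ECE in [0, 1]; NA for an all-empty table.
#' @export
ece <- function(table) {
  n <- sum(table$count)
  if (n == 0) return(NA_real_)
  occ <- table$count > 0
  sum(table$count[occ] / n * abs(table$accuracy[occ] - table$confidence[occ]))
}

#' Brier skill score against the climatology reference
#'
#' `BSS = 1 - BS / BS_ref`, where BS is the mean squared error of the
#' probabilities against the binary outcomes and BS_ref is the Brier
#' score of the constant climatology forecast at the positive-class
#' prevalence, `p(1-p)`. Positive values beat the reference; the
#' maximum is 1 (perfect forecast).
#'
#' @inheritParams reliability
#' @return BSS (<= 1); NA when the labels are single-class (BS_ref = 0,
#'   undefined).
#' @export
brier_skill_score <- function(probs, labels) {
  labels <- as.integer(labels > 0)
  pbar <- mean(labels)
  bs_ref <- pbar * (1 - pbar)
  if (bs_ref == 0) return(NA_real_)
  bs <- mean((probs - labels)^2)
  1 - bs / bs_ref
}

## Horizon relabeling: epoch at time t is positive iff a seizure onsets
## within [t + sph, t + sph + sop). Epochs whose look-ahead extends
## past the record end without an onset are dropped (right-censored).
horizon_labels <- function(trace, events, sph_s, sop_s) {
  t0 <- trace$epoch_start_s
  pos <- rep(FALSE, length(t0))
  if (nrow(events))
    for (e in seq_len(nrow(events)))
      pos <- pos | (events$onset_s[e] >= t0 + sph_s &
                    events$onset_s[e] < t0 + sph_s + sop_s)
  censored <- (t0 + sph_s + sop_s > trace$record_end_s) & !pos
  list(label = as.integer(pos), keep = !censored)
}

#' Calibration and skill over an SPH x SOP grid
#'
#' For every grid cell, epochs are relabeled by horizon (positive iff a
#' seizure onsets within `[t + sph, t + sph + sop)`), right-censored
#' epochs are dropped, predictions are pooled across subjects, and the
#' Brier skill score (plus ECE and prevalence) is computed. Cells whose
#' pooled labels are single-class report NA.
#'
#' @param traces list of `"prediction_trace"`s.
#' @param events_by_subject named list of event data.frames (merged per
#'   cell's SPH internally).
#' @param sph_grid,sop_grid grid values in seconds.
#' @param n_bins reliability bins for the per-cell ECE.
#' @return data.frame with one row per cell: sph_s, sop_s, bss, ece,
#'   brier, prevalence, n.
#' @export
bss_grid <- function(traces, events_by_subject,
                     sph_grid = seq(60, 420, by = 60),
                     sop_grid = c(seq(60, 420, by = 60), 600),
                     n_bins = 10L) {
  rows <- list()
  for (sph in sph_grid) for (sop in sop_grid) {
    probs <- numeric(0); labs <- integer(0)
    for (tr in traces) {
      ev <- merge_close_seizures(events_by_subject[[tr$subject_id]] %||%
                                   events_df(), sph)
      hl <- horizon_labels(tr, ev, sph, sop)
      probs <- c(probs, tr$preictal_prob[hl$keep])
      labs <- c(labs, hl$label[hl$keep])
    }
    single <- length(unique(labs)) < 2
    rows[[length(rows) + 1L]] <- data.frame(
      sph_s = sph, sop_s = sop,
      bss = if (single) NA_real_ else brier_skill_score(probs, labs),
      ece = if (length(labs)) ece(reliability(probs, labs, n_bins)) else NA_real_,
      brier = if (length(labs)) mean((probs - labs)^2) else NA_real_,
      prevalence = if (length(labs)) mean(labs) else NA_real_,
      n = length(labs))
  }
  do.call(rbind, rows)
}
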