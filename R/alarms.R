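#' Alarm-system configuration
#'
#' @param sph_s seizure prediction horizon: minimum lead time between
#'   an alarm and the start of the period in which the seizure is
#'   expected, seconds (>= 0).
#' @param sop_s seizure occurrence period: the window after the SPH
#'   during which the predicted seizure is expected, seconds (> 0).
#' @param threshold preictal-probability decision threshold in [0, 1].
#' @return A list of class `"alarm_config"`.
#' @export
alarm_config <- function(sph_s = 180, sop_s = 420, threshold = 0.5) {
  if (sph_s < 0 || sop_s <= 0) stop("need sph_s >= 0 and sop_s > 0")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(list(sph_s = sph_s, sop_s = sop_s, threshold = threshold),
            class = "alarm_config")
}

#' Raise SPH/SOP alarms from a prediction trace
#'
#' Walking the epoch grid in time order, an alarm triggers at the first
#' epoch whose probability exceeds the threshold while no alarm is
#' active; it stays active for `sph_s + sop_s` (the alarm warning
#' period), suppressing re-triggers, and the next trigger is eligible
#' at the first epoch at or after its expiry. An alarm triggered at
#' time t is a true positive iff some seizure onsets within its warning
#' window `[t + sph, t + sph + sop)`; otherwise a false positive. A
#' seizure whose onset no warning window covers is a false negative.
#'
#' Events must already be merged with [merge_close_seizures()] at this
#' SPH.
#'
#' @param trace a `"prediction_trace"`.
#' @param cfg an [alarm_config()].
#' @param events merged seizure events for the subject.
#' @return A list of class `"alarm_track"`: `alarms` (trigger_s,
#'   warn_start_s, warn_end_s, outcome), `state` (per-epoch
#'   `"true_alarm"`/`"false_alarm"`/`"none"`), `fn_events`, plus the
#'   epoch grid and config.
#' @export
raise_alarms <- function(trace, cfg, events) {
  stopifnot(inherits(trace, "prediction_trace"), inherits(cfg, "alarm_config"))
  events <- check_events(events)
  times <- trace$epoch_start_s
  span <- cfg$sph_s + cfg$sop_s
  cand <- which(trace$preictal_prob > cfg$threshold)
  trig <- numeric(0)
  i <- if (length(cand)) 1L else 0L
  while (i >= 1L && i <= length(cand)) {
    t0 <- times[cand[i]]
    trig <- c(trig, t0)
    nxt <- which(times[cand] >= t0 + span)
    i <- if (length(nxt)) nxt[1] else 0L
  }
  warn_start <- trig + cfg$sph_s
  warn_end <- trig + span
  outcome <- vapply(seq_along(trig), function(a)
    if (nrow(events) && any(events$onset_s >= warn_start[a] &
                            events$onset_s < warn_end[a]))
      "true_positive" else "false_positive", "")
  covered <- rep(FALSE, nrow(events))
  if (nrow(events) && length(trig))
    for (a in seq_along(trig))
      covered <- covered | (events$onset_s >= warn_start[a] &
                            events$onset_s < warn_end[a])
  state <- rep("none", length(times))
  for (a in seq_along(trig)) {
    inside <- times >= trig[a] & times < trig[a] + span
    state[inside] <- if (outcome[a] == "true_positive") "true_alarm" else
      "false_alarm"
  }
  structure(list(
    alarms = data.frame(trigger_s = trig, warn_start_s = warn_start,
                        warn_end_s = warn_end, outcome = outcome),
    state = state,
    fn_events = events[!covered, , drop = FALSE],
    events = events,
    epoch_start_s = times,
    epoch_len_s = trace$epoch_len_s,
    censor_flag = trace$censor_flag,
    config = cfg), class = "alarm_track")
}

#' Time-point confusion tally of an alarm track
#'
#' Counts evaluable time points (the non-burn-in epoch grid, optionally
#' without right-censored epochs) in true-alarm, false-alarm and
#' no-alarm states. For the time-point sensitivity denominator, missed
#' seizures contribute the window `[onset - sph - sop, onset - sph)` a
#' correct alarm would have occupied (`miss_time_s`).
#'
#' @param track an [raise_alarms()] result.
#' @param exclude_censored drop epochs flagged right-censored from all
#'   time totals.
#' @return A list of class `"confusion_tally"`.
#' @export
tally <- function(track, exclude_censored = TRUE) {
  stopifnot(inherits(track, "alarm_track"))
  keep <- if (exclude_censored) !track$censor_flag else
    rep(TRUE, length(track$state))
  len <- track$epoch_len_s
  st <- track$state[keep]
  times <- track$epoch_start_s[keep]
  tp_time <- sum(st == "true_alarm") * len
  fp_time <- sum(st == "false_alarm") * len
  total <- length(st) * len
  cfg <- track$config
  miss_time <- 0
  if (nrow(track$fn_events))
    for (e in seq_len(nrow(track$fn_events))) {
      on <- track$fn_events$onset_s[e]
      miss_time <- miss_time +
        sum(times >= on - cfg$sph_s - cfg$sop_s & times < on - cfg$sph_s) * len
    }
  structure(list(tp_time_s = tp_time, fp_time_s = fp_time,
                 tn_time_s = total - tp_time - fp_time,
                 fn_count = nrow(track$fn_events),
                 miss_time_s = miss_time,
                 time_in_true_alarm_s = tp_time,
                 total_time_s = total,
                 n_alarms = nrow(track$alarms),
                 n_fp_alarms = sum(track$alarms$outcome == "false_positive"),
                 n_seizures = nrow(track$events)),
            class = "confusion_tally")
}

## Element-wise sum of tallies (pooling subjects, micro-average).
pool_tallies <- function(tallies) {
  out <- tallies[[1]]
  for (t in tallies[-1])
    for (nm in names(out)) out[[nm]] <- out[[nm]] + t[[nm]]
  out
}

#' Time-point sensitivity (Proix-style)
#'
#' Time points in alarms with correctly predicted seizures divided by
#' all time points in alarm states associated with seizures (true-alarm
#' time plus the hypothetical windows of missed seizures).
#'
#' @param t a `"confusion_tally"`.
#' @return Proportion in [0, 1]; NA when no seizure-associated time
#'   exists (undefined, reported missing).
#' @export
sensitivity <- function(t) {
  denom <- t$tp_time_s + t$miss_time_s
  if (denom <= 0) return(NA_real_)
  t$tp_time_s / denom
}

#' Corrected proportion of time in warning
#'
#' `(TIW - time in true alarm states) / (total time - time in true
#' alarm states)`: the fraction of non-seizure-warranted time spent
#' under (false) warning.
#'
#' @param t a `"confusion_tally"`.
#' @return Proportion in [0, 1].
#' @export
corrected_tiw <- function(t) {
  if (t$total_time_s <= t$time_in_true_alarm_s)
    stop("degenerate tally: no time outside true alarms")
  tiw <- t$tp_time_s + t$fp_time_s
  (tiw - t$time_in_true_alarm_s) / (t$total_time_s - t$time_in_true_alarm_s)
}

#' False detection rate per hour
#'
#' Count of false-positive alarms divided by evaluable monitoring hours.
#'
#' @param track an `"alarm_track"` (or a `"confusion_tally"`).
#' @param total_time_s evaluable time in seconds; defaults to the
#'   track's epoch grid span.
#' @return Alarms per hour (>= 0).
#' @export
fdr_per_hour <- function(track, total_time_s = NULL) {
  if (inherits(track, "confusion_tally")) {
    n_fp <- track$n_fp_alarms
    total_time_s <- total_time_s %||% track$total_time_s
  } else {
    n_fp <- sum(track$alarms$outcome == "false_positive")
    total_time_s <- total_time_s %||%
      (length(track$state) * track$epoch_len_s)
  }
  if (total_time_s <= 0) stop("total_time_s must be positive")
  n_fp / (total_time_s / 3600)
}

#' Threshold sweep of the alarm system
#'
#' Re-raises alarms at each threshold of a dense grid (101 evenly
#' spaced values plus every observed probability, by default), pooling
#' time-point tallies across subjects, and derives ROC and
#' precision-recall curves: TPR is the Proix time-point sensitivity,
#' FPR the false-warning fraction of time outside true alarms (the
#' corrected TIW), precision the true-alarm fraction of all alarm
#' time. AUROC integrates the ROC by trapezoid; AUPRC uses step-wise
#' interpolation. The reported baseline AUPRC is the
#' seizure-associated fraction of time under no alarms.
#'
#' @param traces list of `"prediction_trace"`s (one per subject).
#' @param events_by_subject named list of raw event data.frames.
#' @param sph_s,sop_s alarm horizon parameters, seconds.
#' @param thresholds optional numeric vector; default 101-point grid
#'   plus observed probabilities.
#' @param exclude_censored passed to [tally()].
#' @return A list of class `"threshold_sweep"`: `curve` (threshold,
#'   tpr, fpr, precision, tiw, fdr_hr), `auroc`, `auprc`,
#'   `baseline_auprc`, `degenerate` flag.
#' @export
threshold_sweep <- function(traces, events_by_subject, sph_s, sop_s,
                            thresholds = NULL, exclude_censored = TRUE) {
  merged <- lapply(events_by_subject, merge_close_seizures, sph_s = sph_s)
  probs <- unlist(lapply(traces, function(tr) tr$preictal_prob))
  degenerate <- length(unique(probs)) < 2
  if (is.null(thresholds))
    thresholds <- sort(unique(c(seq(0, 1, length.out = 101), probs)))
  rows <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    th <- min(max(thresholds[k], 0), 1)
    tl <- pool_tallies(lapply(seq_along(traces), function(i) {
      cfg <- alarm_config(sph_s, sop_s, th)
      tally(raise_alarms(traces[[i]], cfg,
                         merged[[traces[[i]]$subject_id]]),
            exclude_censored = exclude_censored)
    }))
    ct <- tryCatch(corrected_tiw(tl), error = function(e) NA_real_)
    rows[[k]] <- data.frame(
      threshold = th,
      tpr = sensitivity(tl),
      fpr = ct,
      precision = if (tl$tp_time_s + tl$fp_time_s > 0)
        tl$tp_time_s / (tl$tp_time_s + tl$fp_time_s) else NA_real_,
      tiw = ct,
      fdr_hr = fdr_per_hour(tl),
      sens = sensitivity(tl))
  }
  curve <- do.call(rbind, rows)
  ok <- is.finite(curve$tpr) & is.finite(curve$fpr)
  roc <- curve[ok, ]
  auroc_v <- if (degenerate || !nrow(roc)) 0.5 else {
    o <- order(roc$fpr, roc$tpr)             # staircase: ties rise first
    fx <- c(0, roc$fpr[o], 1)
    fy <- c(0, roc$tpr[o], 1)
    sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  }
  ## step-interpolated PR area over increasing recall
  pr <- curve[is.finite(curve$tpr) & is.finite(curve$precision), ]
  auprc_v <- if (nrow(pr)) {
    o <- order(pr$tpr)
    r <- c(0, pr$tpr[o]); p <- c(pr$precision[o][1], pr$precision[o])
    sum(diff(r) * p[-1])
  } else NA_real_
  ## baseline: seizure-associated fraction of time with no alarms raised
  tl0 <- pool_tallies(lapply(seq_along(traces), function(i) {
    cfg <- alarm_config(sph_s, sop_s, 1)
    tr <- traces[[i]]; tr$preictal_prob <- rep(0, length(tr$preictal_prob))
    tally(raise_alarms(tr, cfg, merged[[tr$subject_id]]),
          exclude_censored = exclude_censored)
  }))
  structure(list(curve = curve, auroc = auroc_v, auprc = auprc_v,
                 baseline_auprc = tl0$miss_time_s / tl0$total_time_s,
                 degenerate = degenerate,
                 sph_s = sph_s, sop_s = sop_s),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> SPH %g s / SOP %g s: AUROC %.3f, AUPRC %.3f (baseline %.3f)%s\n",
              x$sph_s, x$sop_s, x$auroc, x$auprc, x$baseline_auprc,
              if (x$degenerate) " [degenerate trace]" else ""))
  invisible(x)
}

#' Alarm metrics over an SPH x SOP grid
#'
#' Runs [threshold_sweep()] in every grid cell (events re-merged per
#' cell's SPH) and reports AUROC, AUPRC, baseline AUPRC, and the
#' corrected TIW and FDR/hr at the threshold whose time-point
#' sensitivity is closest to `target_sensitivity`. Pooled
#' (micro-averaged) across subjects; emitted as a tidy table for
#' heatmap plotting.
#'
#' @inheritParams threshold_sweep
#' @param sph_grid,sop_grid vectors of SPH and SOP values, seconds.
#' @param n_thresholds size of the per-cell threshold grid.
#' @param target_sensitivity operating point for TIW / FDR readouts.
#' @return data.frame with one row per (sph_s, sop_s) cell.
#' @export
grid_sweep <- function(traces, events_by_subject,
                       sph_grid = seq(60, 420, by = 60),
                       sop_grid = seq(60, 420, by = 60),
                       n_thresholds = 33, target_sensitivity = 0.8,
                       exclude_censored = TRUE) {
  rows <- list()
  for (sph in sph_grid) for (sop in sop_grid) {
    sw <- threshold_sweep(traces, events_by_subject, sph, sop,
                          thresholds = seq(0, 1, length.out = n_thresholds),
                          exclude_censored = exclude_censored)
    op <- sw$curve[is.finite(sw$curve$sens), ]
    tiw <- fdr <- NA_real_
    if (nrow(op)) {
      i <- which.min(abs(op$sens - target_sensitivity))
      tiw <- op$tiw[i]; fdr <- op$fdr_hr[i]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sph_s = sph, sop_s = sop, auroc = sw$auroc, auprc = sw$auprc,
      baseline_auprc = sw$baseline_auprc,
      tiw_at_target = tiw, fdr_hr_at_target = fdr)
  }
  do.call(rbind, rows)
}
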