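#' Merge seizures closer than the prediction horizon
#'
#' Successive events whose gap (next onset minus previous offset) is
#' strictly less than `sph_s` are treated as a single seizure event
#' spanning both. Applied before epoch labeling and alarm scoring.
#'
#' @param events sorted half-open event data.frame (onset_s, offset_s).
#' @param sph_s seizure prediction horizon, seconds.
#' @return Merged, sorted, non-overlapping event data.frame.
#' @export
merge_close_seizures <- function(events, sph_s) {
  events <- check_events(events)
  if (nrow(events) <= 1L) return(events)
  on <- events$onset_s; off <- events$offset_s
  m_on <- on[1]; m_off <- off[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in 2:length(on)) {
    if (on[i] - m_off < sph_s) {
      m_off <- max(m_off, off[i])
    } else {
      out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  events_df(c(out_on, m_on), c(out_off, m_off))
}

#' Label fixed-length epochs as ictal / preictal / interictal / excluded
#'
#' Segments the recording timeline into consecutive `epoch_len_s`
#' epochs and assigns one state per epoch:
#' \itemize{
#'   \item \strong{ictal}: the epoch overlaps any seizure event;
#'   \item \strong{preictal}: fully inside
#'     `[onset - preictal_start_s, onset - preictal_end_s)` of some
#'     event (default 6 to 1 minutes before onset) and not ictal;
#'   \item \strong{interictal}: fully inside
#'     `[previous offset + post_sz_buffer_s, next onset - preictal_start_s)`
#'     (default 1 min after a seizure to 6 min before the next, keeping
#'     the classes disjoint; the record start and end act as open
#'     boundaries);
#'   \item \strong{excluded}: everything else (buffer zones and epochs
#'     straddling a state boundary).
#' }
#'
#' Trailing samples that do not fill a whole epoch are dropped.
#'
#' @param rec an [recording()] (only its duration is used), or a
#'   duration in seconds.
#' @param events merged, sorted seizure events.
#' @param epoch_len_s epoch length, seconds.
#' @param preictal_start_s,preictal_end_s preictal window boundaries,
#'   seconds before onset.
#' @param post_sz_buffer_s interictal guard after a seizure offset, s.
#' @param subject_id subject id stored per epoch.
#' @return data.frame of class `"epoch_frame"`: subject_id,
#'   epoch_start_s, epoch_len_s, label (factor), censor_flag; with the
#'   record duration as attribute `record_end_s`.
#' @export
label_epochs <- function(rec, events, epoch_len_s = 20,
                         preictal_start_s = 360, preictal_end_s = 60,
                         post_sz_buffer_s = 60,
                         subject_id = NULL) {
  dur <- if (inherits(rec, "eeg_recording")) duration_s(rec) else as.numeric(rec)
  if (is.null(subject_id))
    subject_id <- if (inherits(rec, "eeg_recording")) rec$subject_id else "S00"
  events <- check_events(events)
  n_ep <- floor(dur / epoch_len_s)
  starts <- (seq_len(n_ep) - 1) * epoch_len_s
  ends <- starts + epoch_len_s
  lab <- rep("excluded", n_ep)

  ## interictal spans: between buffered offsets and preictal starts
  bounds_lo <- c(0, events$offset_s + post_sz_buffer_s)
  bounds_hi <- c(events$onset_s - preictal_start_s, dur)
  inter_ok <- rep(FALSE, n_ep)
  for (k in seq_along(bounds_lo))
    inter_ok <- inter_ok | interval_inside(starts, ends, bounds_lo[k], bounds_hi[k])
  lab[inter_ok] <- "interictal"

  if (nrow(events) > 0L) {
    ## preictal windows of nearby seizures may overlap; their union is
    ## what "within 6-1 min of an upcoming onset" means second-wise
    pw <- merge_intervals(events$onset_s - preictal_start_s,
                          events$onset_s - preictal_end_s)
    pre_ok <- rep(FALSE, n_ep)
    ict <- rep(FALSE, n_ep)
    for (k in seq_len(nrow(pw)))
      pre_ok <- pre_ok | interval_inside(starts, ends, pw$lo[k], pw$hi[k])
    for (e in seq_len(nrow(events)))
      ict <- ict | intervals_overlap(starts, ends,
                                     events$onset_s[e], events$offset_s[e])
    lab[pre_ok] <- "preictal"
    lab[ict] <- "ictal"
  }
  out <- data.frame(subject_id = subject_id,
                    epoch_start_s = starts,
                    epoch_len_s = epoch_len_s,
                    label = factor(lab, levels = epoch_label_levels),
                    censor_flag = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "record_end_s") <- dur
  class(out) <- c("epoch_frame", class(out))
  out
}

epoch_label_levels <- c("ictal", "preictal", "interictal", "excluded")

#' Exclude right-censored epochs
#'
#' A non-ictal epoch whose look-ahead window
#' `[epoch_end, epoch_end + horizon_s)` extends past the record end
#' without an intervening seizure onset has an unknowable outcome and
#' is flagged excluded.
#'
#' @param epochs an `"epoch_frame"` from [label_epochs()].
#' @param events merged seizure events of the same subject.
#' @param horizon_s look-ahead horizon in seconds (SPH + SOP of the
#'   evaluation in use); 0 excludes nothing.
#' @return The epoch frame with censored epochs relabeled `excluded`
#'   and `censor_flag` set.
#' @export
exclude_right_censored <- function(epochs, events, horizon_s) {
  stopifnot(horizon_s >= 0)
  events <- check_events(events)
  dur <- attr(epochs, "record_end_s")
  ends <- epochs$epoch_start_s + epochs$epoch_len_s
  past_end <- ends + horizon_s > dur
  covered <- rep(FALSE, nrow(epochs))
  if (nrow(events) > 0L)
    for (e in seq_len(nrow(events)))
      covered <- covered | (events$onset_s[e] >= ends & events$onset_s[e] < dur)
  censor <- past_end & !covered & epochs$label != "ictal"
  epochs$censor_flag <- epochs$censor_flag | censor
  epochs$label[censor] <- "excluded"
  epochs
}
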