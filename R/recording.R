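#' Multichannel EEG recording
#'
#' Container for a block of multichannel EEG signal. Rows of `signal` are
#' channels (referential electrodes or bipolar derivations), columns are
#' samples at a common sampling rate. Amplitudes are in microvolts.
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per signal row.
#' @param subject_id subject identifier.
#' @param start_time_s offset of the first sample from the nominal record
#'   start, in seconds. Zero for complete recordings.
#' @return An object of class `"eeg_recording"`.
#' @export
recording <- function(signal, fs, channel_labels, subject_id = "S00",
                      start_time_s = 0) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric")
  if (length(channel_labels) != nrow(signal))
    stop("channel_labels length (", length(channel_labels),
         ") must equal signal row count (", nrow(signal), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  rownames(signal) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id),
         channel_labels = as.character(channel_labels),
         fs = as.numeric(fs),
         signal = signal,
         start_time_s = as.numeric(start_time_s)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f min)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs / 60))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$fs

n_channels <- function(rec) nrow(rec$signal)
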