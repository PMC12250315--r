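#' Band-pass filter and resample a recording
#'
#' Applies the standard neonatal preprocessing: a zero-phase band-pass
#' (realized as separate 4th-order Butterworth high-pass and low-pass
#' filters run forward-backward with [signal::filtfilt()], which keeps
#' the very low 0.1 Hz edge numerically stable) followed by polyphase
#' resampling to `target_fs`. Electromyogenic and line artifacts
#' dominate neonatal ICU EEG above 20 Hz, hence the default band.
#'
#' @param rec an [recording()].
#' @param low_hz high-pass edge, Hz.
#' @param high_hz low-pass edge, Hz; requires `rec$fs >= 2*high_hz`.
#' @param target_fs output sampling rate, Hz.
#' @return A new [recording()] at `target_fs`; duration preserved to
#'   within one sample.
#' @export
preprocess <- function(rec, low_hz = 0.1, high_hz = 20, target_fs = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs < 2 * high_hz)
    stop(sprintf("fs = %g Hz cannot honor a %g Hz band (need fs >= %g)",
                 rec$fs, high_hz, 2 * high_hz))
  nyq <- rec$fs / 2
  bl <- signal::butter(4, high_hz / nyq, type = "low")
  bh <- signal::butter(4, low_hz / nyq, type = "high")
  sig <- rec$signal
  for (ch in seq_len(nrow(sig))) {
    x <- signal::filtfilt(bl, sig[ch, ])
    sig[ch, ] <- signal::filtfilt(bh, x)
  }
  if (target_fs != rec$fs) {
    frac <- ratio_approx(target_fs / rec$fs)
    n_out <- ceiling(ncol(sig) * frac[1] / frac[2])
    out <- matrix(0, nrow(sig), n_out)
    for (ch in seq_len(nrow(sig)))
      out[ch, ] <- signal::resample(sig[ch, ], frac[1], frac[2])[seq_len(n_out)]
    sig <- out
  }
  recording(sig, target_fs, rec$channel_labels, rec$subject_id,
            rec$start_time_s)
}
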