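## EDF (European Data Format) reader/writer.
##
## EDF stores a 256-byte ASCII header, 256 ASCII bytes of per-signal
## headers per signal (field-major), then little-endian int16 data
## records. Physical values are reconstructed linearly from the
## digital range, so a write/read round trip is exact only up to the
## 16-bit quantization step (physical range / digital range).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_read_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n)
  if (length(raw) < n)
    stop("truncated EDF header at byte offset ", seek(con), call. = FALSE)
  trimws(rawToChar(raw))
}

#' Write a recording to an EDF file
#'
#' Signals are scaled channel-wise to the full 16-bit digital range.
#' Channel labels are written as `"EEG <label>"`; the data-record
#' duration is 1 s, so `fs` must be a positive integer and the signal
#' is zero-padded to a whole number of seconds.
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- nrow(rec$signal)
  n_rec <- ceiling(ncol(rec$signal) / fs)
  sig <- rec$signal
  if (ncol(sig) < n_rec * fs)
    sig <- cbind(sig, matrix(0, ns, n_rec * fs - ncol(sig)))
  pmax_ <- apply(abs(sig), 1, max)
  pmax_ <- ifelse(pmax_ == 0, 1, pmax_ * 1.0001)
  ## headers carry limits at 2 decimals; scale with the stored value so
  ## reader and writer agree exactly
  pmax_ <- ceiling(pmax_ * 100) / 100
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8), edf_pad(rec$subject_id, 80), edf_pad("seizecast", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)),
    con, eos = NULL)
  fields <- list(
    c(vapply(rec$channel_labels, function(l) edf_pad(paste("EEG", l), 16), "")),
    rep(edf_pad("AgAgCl electrode", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(-pmax_, function(v) edf_pad(sprintf("%.2f", v), 8), ""),
    vapply(pmax_, function(v) edf_pad(sprintf("%.2f", v), 8), ""),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(fs, 8), ns),
    rep(edf_pad("", 32), ns))
  writeChar(paste(unlist(fields), collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((sig[ch, idx] + pmax_[ch]) * scale[ch]) + dmin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Returns all EEG-typed channels (label beginning `"EEG"`); other
#' signal types (ECG, EMG, annotations, ...) are dropped with a
#' warning. If EEG channels carry mixed sampling rates, all are
#' resampled to the minimum rate with a warning.
#'
#' @param path EDF file path.
#' @param subject_id subject id for the returned recording; defaults to
#'   the file's patient-identification field.
#' @return An [recording()].
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  edf_read_ascii(con, 8)                       # version
  patient <- edf_read_ascii(con, 80)
  edf_read_ascii(con, 80)                      # recording id
  edf_read_ascii(con, 8); edf_read_ascii(con, 8)  # date, time
  edf_read_ascii(con, 8)                       # header bytes
  edf_read_ascii(con, 44)
  n_rec <- as.integer(edf_read_ascii(con, 8))
  rec_dur <- as.numeric(edf_read_ascii(con, 8))
  ns <- as.integer(edf_read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad signal count")

  rd <- function(w) vapply(seq_len(ns), function(i) edf_read_ascii(con, w), "")
  labels <- rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8)); rd(32)

  is_eeg <- startsWith(toupper(labels), "EEG")
  if (!all(is_eeg))
    warning("dropping non-EEG channels: ",
            paste(labels[!is_eeg], collapse = ", "))
  if (!any(is_eeg)) stop("EDF contains no EEG channels")

  data <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", per_rec, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(block) < per_rec)
      stop("truncated EDF data at byte offset ", seek(con),
           " (record ", r, " of ", n_rec, ")", call. = FALSE)
    off <- 0L
    for (i in seq_len(ns)) {
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        block[(off + 1L):(off + spr[i])]
      off <- off + spr[i]
    }
  }
  keep <- which(is_eeg)
  fs_all <- spr[keep] / rec_dur
  fs <- min(fs_all)
  if (length(unique(fs_all)) > 1L)
    warning("mixed EEG sampling rates; resampling all channels to ",
            fs, " Hz")
  sig <- matrix(0, length(keep), round(n_rec * rec_dur * fs))
  for (j in seq_along(keep)) {
    i <- keep[j]
    phys <- (data[[i]] - dmin[i]) * (pmax_[i] - pmin_[i]) /
      (dmax[i] - dmin[i]) + pmin_[i]
    if (fs_all[j] != fs) {
      frac <- ratio_approx(fs / fs_all[j])
      phys <- signal::resample(phys, frac[1], frac[2])
    }
    sig[j, seq_len(min(ncol(sig), length(phys)))] <-
      phys[seq_len(min(ncol(sig), length(phys)))]
  }
  labs <- trimws(sub("^EEG", "", labels[keep]))
  recording(sig, fs, labs, subject_id = subject_id %||% patient)
}

## Small-denominator rational approximation p/q of a positive ratio.
ratio_approx <- function(x, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  best
}
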