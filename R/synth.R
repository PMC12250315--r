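#' Configuration for the synthetic neonatal-EEG cohort generator
#'
#' Describes a cohort of simulated neonatal EEG recordings: background
#' activity with 1/f spectral decay and hemispherically correlated
#' channels, superimposed rhythmic seizure discharges, multi-rater
#' annotations with boundary jitter, and an optional planted preictal
#' signature (a linear ramp of 8-20 Hz band-power shift and variance
#' inflation over the minutes preceding each seizure onset).
#'
#' The defaults emulate the event statistics of public neonatal cohorts
#' at reduced scale: ~1 h records, seizure durations lognormal with
#' median 74 s and sdlog 1.04 (truncated to 15-300 s), 2-4 seizures per
#' seizure subject with at least 6 min between events, three annotators.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param seizure_subject_fraction proportion of subjects with seizures.
#' @param record_duration record length per subject, seconds.
#' @param fs sampling rate of the generated raw signal, Hz (>= 40).
#' @param n_channels even channel count; channels come in homologous
#'   left/right 10-20 pairs (F3/F4, C3/C4, O1/O2, T3/T4, ...).
#' @param seizures_min,seizures_max per-subject seizure count is drawn
#'   uniformly from `seizures_min:seizures_max`.
#' @param seizure_duration_median_s,seizure_duration_sdlog lognormal
#'   seizure duration parameters (median in seconds, sd of log duration).
#' @param seizure_duration_range_s truncation bounds for durations, seconds.
#' @param min_interseizure_gap_s minimum gap between an offset and the
#'   next onset, seconds.
#' @param preictal_strength non-negative scalar scaling the planted
#'   preictal signature; 0 plants nothing, leaving preictal and
#'   interictal segments statistically exchangeable.
#' @param preictal_span_s length of the planted ramp before each onset,
#'   seconds (truncated at record start).
#' @param n_raters number of simulated annotators.
#' @param rater_noise_s maximum per-boundary annotation jitter, seconds.
#' @param background_sd_uv background amplitude scale (standard
#'   deviation), microvolts.
#' @param seed integer seed; fixes every generated array and event list.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_subjects = 12,
                         seizure_subject_fraction = 0.5,
                         record_duration = 3600,
                         fs = 64,
                         n_channels = 8,
                         seizures_min = 2,
                         seizures_max = 4,
                         seizure_duration_median_s = 74,
                         seizure_duration_sdlog = 1.04,
                         seizure_duration_range_s = c(15, 300),
                         min_interseizure_gap_s = 360,
                         preictal_strength = 0,
                         preictal_span_s = 300,
                         n_raters = 3,
                         rater_noise_s = 5,
                         background_sd_uv = 25,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              seizure_subject_fraction = seizure_subject_fraction,
              record_duration = record_duration,
              fs = fs, n_channels = as.integer(n_channels),
              seizures_min = as.integer(seizures_min),
              seizures_max = as.integer(seizures_max),
              seizure_duration_median_s = seizure_duration_median_s,
              seizure_duration_sdlog = seizure_duration_sdlog,
              seizure_duration_range_s = seizure_duration_range_s,
              min_interseizure_gap_s = min_interseizure_gap_s,
              preictal_strength = preictal_strength,
              preictal_span_s = preictal_span_s,
              n_raters = as.integer(n_raters),
              rater_noise_s = rater_noise_s,
              background_sd_uv = background_sd_uv,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_channels %% 2L != 0L || cfg$n_channels < 2L)
    stop("n_channels must be even and >= 2 (homologous left/right pairs)")
  if (cfg$n_channels > 16L)
    stop("at most 16 channels (8 homologous 10-20 pairs) are supported")
  if (cfg$record_duration <= 0) stop("record_duration must be positive")
  if (cfg$fs < 40) stop("fs must be >= 40 Hz")
  if (cfg$preictal_strength < 0) stop("preictal_strength must be >= 0")
  if (cfg$seizure_subject_fraction < 0 || cfg$seizure_subject_fraction > 1)
    stop("seizure_subject_fraction must lie in [0,1]")
  if (cfg$n_raters < 1) stop("n_raters must be >= 1")
  invisible(cfg)
}

## Homologous 10-20 pairs, left then right, in chain-friendly order.
synth_channel_labels <- function(n_channels) {
  pairs <- list(c("F3", "F4"), c("C3", "C4"), c("O1", "O2"), c("T3", "T4"),
                c("Fp1", "Fp2"), c("P3", "P4"), c("F7", "F8"), c("T5", "T6"))
  unlist(pairs[seq_len(n_channels / 2L)])
}

## Real-valued noise with power spectral density ~ 1/f, generated by
## shaping white Gaussian noise in the frequency domain. Power is
## flattened below `f_floor` to keep low-frequency variance finite.
pink_noise <- function(n, fs, f_floor = 0.5) {
  x <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                      # two-sided |frequency|
  h <- 1 / sqrt(pmax(f, f_floor))
  h[1L] <- 0                                # remove DC
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate background EEG for one subject
#'
#' Produces 1/f-weighted Gaussian background with higher inter-channel
#' correlation within homologous left/right pairs (shared hemispheric
#' component) than across pairs (global component only). Amplitudes are
#' scaled to `background_sd_uv` microvolts.
#'
#' @param config a [synth_config()].
#' @param subject_index 1-based subject index; seeds the subject's
#'   private RNG stream.
#' @return An [recording()] of `n_channels x record_duration*fs` samples.
#' @export
generate_background <- function(config, subject_index = 1L) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, subject_index * 3L))
  n <- round(config$record_duration * config$fs)
  labs <- synth_channel_labels(config$n_channels)
  ## variance split: global 0.2, pair-shared 0.4, individual 0.4
  ## => homologous correlation 0.6, non-homologous 0.2
  g <- pink_noise(n, config$fs)
  sig <- matrix(0, config$n_channels, n)
  for (p in seq_len(config$n_channels / 2L)) {
    shared <- pink_noise(n, config$fs)
    for (side in 1:2) {
      i <- (p - 1L) * 2L + side
      own <- pink_noise(n, config$fs)
      sig[i, ] <- sqrt(0.2) * g + sqrt(0.4) * shared + sqrt(0.4) * own
    }
  }
  sig <- sig * config$background_sd_uv
  recording(sig, config$fs, labs,
            subject_id = sprintf("S%02d", subject_index))
}

## Truncated lognormal seizure durations (seconds).
draw_seizure_durations <- function(n, cfg) {
  lo <- cfg$seizure_duration_range_s[1]; hi <- cfg$seizure_duration_range_s[2]
  d <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      di <- stats::rlnorm(1, meanlog = log(cfg$seizure_duration_median_s),
                          sdlog = cfg$seizure_duration_sdlog)
      if (di >= lo && di <= hi) { d[i] <- di; break }
    }
  }
  round(d)
}

## Place n events of the given durations with gaps >= gap_s, uniformly
## over the feasible arrangements (stick-breaking over the slack time).
place_events <- function(durations, total_s, gap_s) {
  n <- length(durations)
  if (n == 0L) return(events_df())
  committed <- sum(durations) + (n - 1L) * gap_s
  slack <- total_s - committed
  if (slack < 0)
    stop(sprintf(paste0("cannot place %d seizures (total %d s + %d s gaps)",
                        " in a %d s record"),
                 n, sum(durations), (n - 1L) * gap_s, round(total_s)))
  cuts <- sort(stats::runif(n, 0, slack))
  onsets <- cuts + c(0, cumsum(durations[-n] + gap_s))
  events_df(onset_s = round(onsets), offset_s = round(onsets) + durations)
}

#' Superimpose seizures (and an optional preictal signature) on a recording
#'
#' Seizures are amplitude-ramped sinusoidal discharges whose frequency
#' chirps from 3 Hz at onset to 1.5 Hz at offset, added on every channel
#' with a random per-channel gain. If `preictal_strength > 0`, each
#' seizure is preceded by a planted window of `preictal_span_s` seconds
#' (truncated at the record start) over which signal variance is
#' inflated and 8-20 Hz band-limited noise is mixed in, both ramping
#' linearly from zero at the window start to full strength at onset.
#'
#' @param rec background [recording()] from [generate_background()].
#' @param config a [synth_config()].
#' @param subject_index subject index used to seed the event stream.
#' @param n_seizures number of seizures to plant; default draws
#'   uniformly from `seizures_min:seizures_max`. Use 0 for a
#'   seizure-free subject.
#' @return A list with elements `recording` (modified copy) and `truth`
#'   (class `"ground_truth"`: `seizure_events`, `planted_preictal_windows`,
#'   `preictal_strength`).
#' @export
inject_seizures <- function(rec, config, subject_index = 1L, n_seizures = NULL) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, subject_index * 3L + 1L))
  if (is.null(n_seizures)) {
    counts <- seq(config$seizures_min, config$seizures_max)
    n_seizures <- counts[sample.int(length(counts), 1L)]
  }
  dur <- duration_s(rec)
  fs <- rec$fs
  sig <- rec$signal
  events <- if (n_seizures > 0L)
    place_events(draw_seizure_durations(n_seizures, config), dur,
                 config$min_interseizure_gap_s)
  else events_df()

  windows <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (nrow(events) > 0L) {
    windows <- data.frame(start_s = pmax(0, events$onset_s - config$preictal_span_s),
                          end_s = events$onset_s)
    s <- config$preictal_strength
    if (s > 0) {
      for (w in seq_len(nrow(windows))) {
        i0 <- floor(windows$start_s[w] * fs) + 1L
        i1 <- floor(windows$end_s[w] * fs)
        idx <- i0:i1
        r <- seq_along(idx) / length(idx)        # linear ramp 0 -> 1
        ## variance inflation
        ramp <- 1 + 0.15 * s * rep(r, each = 1L)
        ## 8-20 Hz band-limited additive drift
        for (ch in seq_len(nrow(sig))) {
          band <- band_limited_noise(length(idx), fs, 8, 20)
          sig[ch, idx] <- sig[ch, idx] * ramp +
            band * (0.2 * s * r * config$background_sd_uv)
        }
      }
    }
    ## ictal discharges: 3 -> 1.5 Hz chirp, raised-sine envelope
    for (e in seq_len(nrow(events))) {
      i0 <- floor(events$onset_s[e] * fs) + 1L
      i1 <- min(ncol(sig), floor(events$offset_s[e] * fs))
      t <- (seq(i0, i1) - i0) / fs
      d <- max(t[length(t)], 1 / fs)
      freq <- 3 - 1.5 * t / d
      phase <- 2 * pi * (3 * t - 0.75 * t^2 / d)
      envelope <- sin(pi * t / d)^2
      wave <- 60 * envelope * sin(phase + stats::runif(1, 0, 2 * pi))
      gain <- stats::runif(nrow(sig), 0.6, 1)
      sig[, i0:i1] <- sig[, i0:i1] + outer(gain, wave)
    }
  }
  out <- rec
  out$signal <- sig
  truth <- structure(list(seizure_events = events,
                          planted_preictal_windows = windows,
                          preictal_strength = config$preictal_strength),
                     class = "ground_truth")
  list(recording = out, truth = truth)
}

## White noise band-passed to [low, high] Hz by FFT masking, unit sd.
band_limited_noise <- function(n, fs, low, high) {
  x <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)
  h <- as.numeric(f >= low & f <= high)
  y <- Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

#' Simulate multi-rater seizure annotations
#'
#' Each rater's per-second binary mask equals ground truth with
#' independent uniform jitter of at most `rater_noise_s` seconds applied
#' to every event boundary. Zero jitter reproduces the truth exactly.
#'
#' @param truth a `"ground_truth"` object from [inject_seizures()].
#' @param config a [synth_config()].
#' @param duration_s record duration in seconds.
#' @param subject_index subject index seeding the annotation stream.
#' @return An [annotation_set()] with `config$n_raters` masks.
#' @export
synth_annotations <- function(truth, config, duration_s, subject_index = 1L) {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, subject_index * 3L + 2L))
  nsec <- ceiling(duration_s)
  masks <- matrix(0L, config$n_raters, nsec)
  ev <- truth$seizure_events
  for (r in seq_len(config$n_raters)) {
    if (nrow(ev) > 0L) for (e in seq_len(nrow(ev))) {
      on <- ev$onset_s[e] + stats::runif(1, -config$rater_noise_s, config$rater_noise_s)
      off <- ev$offset_s[e] + stats::runif(1, -config$rater_noise_s, config$rater_noise_s)
      on <- max(0, min(on, nsec - 1))
      off <- max(on + 1, min(off, nsec))
      masks[r, ] <- masks[r, ] | mask_from_events(events_df(on, off), nsec)
    }
  }
  annotation_set(masks)
}

#' Simulate a full cohort
#'
#' Runs background generation, seizure injection and annotation for
#' every subject. The first `round(seizure_subject_fraction * n_subjects)`
#' subjects carry seizures; the rest are seizure-free.
#'
#' @param config a [synth_config()].
#' @return A list of class `"synth_cohort"`: one element per subject with
#'   fields `recording`, `truth`, `annotations`, `has_seizure`.
#' @export
simulate_cohort <- function(config) {
  validate_synth_config(config)
  n_sz <- round(config$seizure_subject_fraction * config$n_subjects)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    bg <- generate_background(config, i)
    nev <- if (i <= n_sz) NULL else 0L
    inj <- inject_seizures(bg, config, i, n_seizures = nev)
    ann <- synth_annotations(inj$truth, config, duration_s(bg), i)
    subjects[[i]] <- list(recording = inj$recording, truth = inj$truth,
                          annotations = ann, has_seizure = i <= n_sz)
  }
  names(subjects) <- vapply(subjects, function(s) s$recording$subject_id, "")
  structure(subjects, class = "synth_cohort", config = config)
}

#' Write a simulated cohort to disk
#'
#' Writes one EDF per subject plus a sidecar annotation CSV
#' (subject, rater, onset_s, offset_s) and a ground-truth JSON.
#'
#' @param cohort a `"synth_cohort"`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_rows <- list()
  truths <- list()
  for (s in cohort) {
    id <- s$recording$subject_id
    write_edf(s$recording, file.path(dir, paste0(id, ".edf")))
    ev <- annotation_events_table(s$annotations, id)
    if (nrow(ev)) ann_rows[[id]] <- ev
    truths[[id]] <- list(
      seizure_events = s$truth$seizure_events,
      planted_preictal_windows = s$truth$planted_preictal_windows,
      preictal_strength = s$truth$preictal_strength)
  }
  ann <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(subject = character(0), rater = integer(0),
               onset_s = numeric(0), offset_s = numeric(0))
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  jsonlite::write_json(truths, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
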