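#' Feature extraction specification
#'
#' Controls the three per-epoch feature families: asymmetry indices of
#' six summary statistics over homologous derivation pairs, Welch band
#' powers per derivation, and recurrence quantification analysis (RQA)
#' per derivation.
#'
#' @param stats summary statistics entering the asymmetry indices.
#' @param bands list of `c(low_hz, high_hz)` band edges; the defaults
#'   are the conventional delta/theta/alpha/beta bands truncated at the
#'   20 Hz filter edge. Bands must be non-overlapping within [0, 20].
#' @param spectral_mode `"absolute"` (log10 band power), `"relative"`
#'   (band power / total 0.5-20 Hz power) or `"both"`.
#' @param rqa_dim,rqa_delay time-delay embedding dimension and delay
#'   (samples).
#' @param rqa_radius_frac recurrence radius as a fraction of the epoch
#'   signal's standard deviation.
#' @param rqa_downsample integer decimation factor applied before
#'   embedding.
#' @param rqa_line_min minimum diagonal/vertical line length.
#' @return A list of class `"feature_spec"`.
#' @export
feature_spec <- function(stats = c("mean", "std", "kurtosis", "skew", "p10", "p90"),
                         bands = list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 20)),
                         spectral_mode = c("both", "absolute", "relative"),
                         rqa_dim = 3L, rqa_delay = 1L,
                         rqa_radius_frac = 0.2, rqa_downsample = 2L,
                         rqa_line_min = 2L) {
  spectral_mode <- match.arg(spectral_mode)
  edges <- do.call(rbind, bands)
  if (any(edges < 0) || any(edges > 20)) stop("bands must lie within [0, 20] Hz")
  o <- order(edges[, 1])
  if (any(edges[o, 2][-nrow(edges)] > edges[o, 1][-1] + 1e-12))
    stop("bands must be non-overlapping")
  if (rqa_radius_frac <= 0 || rqa_dim < 1 || rqa_delay < 1)
    stop("invalid RQA parameters")
  structure(list(stats = stats, bands = bands, spectral_mode = spectral_mode,
                 rqa_dim = as.integer(rqa_dim), rqa_delay = as.integer(rqa_delay),
                 rqa_radius_frac = rqa_radius_frac,
                 rqa_downsample = as.integer(rqa_downsample),
                 rqa_line_min = as.integer(rqa_line_min)),
            class = "feature_spec")
}

#' Six summary statistics of an epoch signal
#'
#' Returns `(mean, std, excess kurtosis, skew, p10, p90)` with
#' population-normalized moments and linearly interpolated percentiles.
#' A constant signal yields kurtosis and skew of 0 (flagged via
#' attribute `degenerate`), never NaN.
#'
#' @param x numeric vector with at least 2 finite samples.
#' @return Named numeric 6-vector.
#' @export
summary_stats <- function(x) {
  stopifnot(length(x) >= 2, all(is.finite(x)))
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  degenerate <- m2 == 0
  std <- sqrt(m2)
  skew <- if (degenerate) 0 else mean(d^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean(d^4) / m2^2 - 3
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE, type = 7)
  out <- c(mean = m, std = std, kurtosis = kurt, skew = skew,
           p10 = q[1], p90 = q[2])
  attr(out, "degenerate") <- degenerate
  out
}

#' Normalized left-right asymmetry index
#'
#' `(L - R) / (|L| + |R| + delta)`: bounded in [-1, 1], scale-free and
#' antisymmetric, with `delta` guarding the zero denominator.
#'
#' @param left_val,right_val finite scalars (vectorized).
#' @param delta denominator guard.
#' @return Asymmetry index in [-1, 1].
#' @export
asymmetry_index <- function(left_val, right_val, delta = 1e-12) {
  (left_val - right_val) / (abs(left_val) + abs(right_val) + delta)
}

## Welch power spectral density: Hann-windowed segments, 50% overlap.
## Returns freq (Hz) and psd (power per Hz).
welch_psd <- function(x, fs, seg_len = min(length(x), round(4 * fs))) {
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  norm <- sum(w^2) * fs
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * norm)
  nf <- floor(seg_len / 2) + 1L
  psd <- psd[seq_len(nf)]
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]      # fold negative freqs
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = psd)
}

#' Welch band-power features of an epoch signal
#'
#' Band powers are integrals of the Welch periodogram over each
#' configured band (bins assigned by `low <= f < high`). Relative
#' powers divide by the total 0.5-20 Hz power, so bands tiling that
#' range sum to 1; absolute powers are log10-scaled. An all-zero signal
#' yields uniform relative powers `1/n_bands` (flagged).
#'
#' @param x epoch signal (>= 4 s of samples).
#' @param fs sampling rate, Hz.
#' @param spec a [feature_spec()].
#' @return Named vector of band powers per the spec's `spectral_mode`.
#' @export
spectral_features <- function(x, fs, spec = feature_spec()) {
  p <- welch_psd(x, fs)
  df <- p$freq[2] - p$freq[1]
  bp <- vapply(spec$bands, function(b)
    sum(p$psd[p$freq >= b[1] & p$freq < b[2]]) * df, 0)
  band_names <- vapply(spec$bands, function(b) sprintf("%g-%g", b[1], b[2]), "")
  total <- sum(p$psd[p$freq >= 0.5 & p$freq < 20]) * df
  rel <- if (total > 0) bp / total else rep(1 / length(bp), length(bp))
  out <- switch(spec$spectral_mode,
    absolute = stats::setNames(log10(bp + 1e-12), paste0("abs_", band_names)),
    relative = stats::setNames(rel, paste0("rel_", band_names)),
    both = c(stats::setNames(log10(bp + 1e-12), paste0("abs_", band_names)),
             stats::setNames(rel, paste0("rel_", band_names))))
  attr(out, "degenerate") <- total <= 0
  out
}

## Run lengths of consecutive points (same group, index step 1) among
## the sparse recurrent-point coordinates.
run_lengths <- function(group, pos) {
  if (!length(group)) return(integer(0))
  new_run <- c(TRUE, diff(group) != 0L | diff(pos) != 1L)
  tabulate(cumsum(new_run))
}

#' Recurrence quantification analysis of an epoch signal
#'
#' Decimates, time-delay embeds the signal, thresholds pairwise
#' distances at `radius_frac * sd(x)` to form the recurrence matrix
#' (main diagonal excluded; Theiler window 1), and returns recurrence
#' rate (RR), determinism (DET: fraction of recurrent points on
#' diagonal lines of length >= `rqa_line_min`), laminarity (LAM:
#' likewise for vertical lines) and mean diagonal line length (L).
#' A constant signal returns RR = DET = LAM = 1 by convention (flagged).
#'
#' @param x epoch signal.
#' @param spec a [feature_spec()].
#' @return Named vector `c(RR, DET, LAM, L)`.
#' @export
rqa_features <- function(x, spec = feature_spec()) {
  xd <- x[seq(1L, length(x), by = spec$rqa_downsample)]
  m <- spec$rqa_dim; tau <- spec$rqa_delay
  npt <- length(xd) - (m - 1L) * tau
  if (npt < 50) stop("too few points after downsampling/embedding (", npt, ")")
  s <- stats::sd(xd)
  if (s == 0) {
    out <- c(RR = 1, DET = 1, LAM = 1, L = npt - 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  emb <- vapply(seq_len(m), function(k) xd[seq_len(npt) + (k - 1L) * tau],
                numeric(npt))
  ## squared-distance threshold via Gram matrix, then sparse coordinates
  n2 <- rowSums(emb^2)
  D2 <- outer(n2, n2, "+") - 2 * tcrossprod(emb)
  idx <- which(D2 <= (spec$rqa_radius_frac * s)^2)
  ii <- (idx - 1L) %% npt + 1L
  jj <- (idx - 1L) %/% npt + 1L
  off <- ii != jj                           # Theiler window 1: drop LOI
  ii <- ii[off]; jj <- jj[off]
  n_rec <- length(ii)
  rr <- n_rec / (npt * (npt - 1))
  if (n_rec == 0) {
    out <- c(RR = 0, DET = 0, LAM = 0, L = 0)
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  ## diagonal lines: runs of consecutive i within a diagonal j - i
  o <- order(jj - ii, ii)
  dlen <- run_lengths((jj - ii)[o], ii[o])
  dlong <- dlen[dlen >= spec$rqa_line_min]
  det <- sum(dlong) / n_rec
  lmean <- if (length(dlong)) mean(dlong) else 0
  ## vertical lines: which() order is already column-major
  vlen <- run_lengths(jj, ii)
  vlong <- vlen[vlen >= spec$rqa_line_min]
  lam <- sum(vlong) / n_rec
  out <- c(RR = rr, DET = det, LAM = lam, L = lmean)
  attr(out, "degenerate") <- FALSE
  out
}

#' Compute the full QEEG feature matrix for labeled epochs
#'
#' Per epoch, concatenates (a) asymmetry indices of the six summary
#' statistics for each homologous left-right derivation pair, (b)
#' spectral features per derivation, and (c) RQA features per
#' derivation, in that fixed column order. Excluded and ictal epochs
#' are featurized too (continuous prediction traces need them) but are
#' masked from training downstream.
#'
#' @param epochs an `"epoch_frame"` from [label_epochs()].
#' @param rec the montaged, preprocessed [recording()] the epochs index
#'   into (nominally 40 Hz).
#' @param montage the [montage_spec()] describing `rec`'s channels.
#' @param spec a [feature_spec()].
#' @return The epoch frame with feature columns appended; the feature
#'   schema (family, channel, parameter) is attached as attribute
#'   `"schema"` and column names as attribute `"feature_names"`.
#' @export
featurize <- function(epochs, rec, montage, spec = feature_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "montage_spec"))
  fs <- rec$fs
  n_ep <- nrow(epochs)
  if (n_ep > 0 &&
      max(epochs$epoch_start_s + epochs$epoch_len_s) * fs > ncol(rec$signal) + 0.5)
    stop("epoch extends past record end")
  schema <- featurize_schema(montage, spec)
  fmat <- matrix(NA_real_, n_ep, nrow(schema),
                 dimnames = list(NULL, schema$column))
  nch <- length(montage$labels)
  for (i in seq_len(n_ep)) {
    i0 <- round(epochs$epoch_start_s[i] * fs) + 1L
    i1 <- round((epochs$epoch_start_s[i] + epochs$epoch_len_s[i]) * fs)
    seg <- rec$signal[, i0:i1, drop = FALSE]
    st <- vapply(seq_len(nch), function(ch) summary_stats(seg[ch, ]),
                 numeric(6))
    vals <- numeric(0)
    for (p in montage$left_right_pairs)
      vals <- c(vals, asymmetry_index(st[, p[1]], st[, p[2]]))
    for (ch in seq_len(nch))
      vals <- c(vals, as.numeric(spectral_features(seg[ch, ], fs, spec)))
    for (ch in seq_len(nch))
      vals <- c(vals, as.numeric(rqa_features(seg[ch, ], spec)))
    fmat[i, ] <- vals
  }
  out <- cbind(epochs, as.data.frame(fmat))
  attr(out, "record_end_s") <- attr(epochs, "record_end_s")
  attr(out, "schema") <- schema
  attr(out, "feature_names") <- schema$column
  class(out) <- c("epoch_frame", "data.frame")
  out
}

## Column schema: family / channel (or pair) / parameter, fixed order.
featurize_schema <- function(montage, spec) {
  rows <- list()
  stat_names <- c("mean", "std", "kurtosis", "skew", "p10", "p90")
  for (p in montage$left_right_pairs) {
    pair <- paste0(montage$labels[p[1]], "|", montage$labels[p[2]])
    rows[[length(rows) + 1L]] <-
      data.frame(family = "asym", channel = pair, parameter = stat_names)
  }
  spec_names <- names(spectral_feature_names(spec))
  for (lab in montage$labels)
    rows[[length(rows) + 1L]] <-
      data.frame(family = "spectral", channel = lab, parameter = spec_names)
  for (lab in montage$labels)
    rows[[length(rows) + 1L]] <-
      data.frame(family = "rqa", channel = lab,
                 parameter = c("RR", "DET", "LAM", "L"))
  schema <- do.call(rbind, rows)
  schema$column <- make.names(paste(schema$family, schema$channel,
                                    schema$parameter, sep = "_"))
  schema
}

spectral_feature_names <- function(spec) {
  band_names <- vapply(spec$bands, function(b) sprintf("%g-%g", b[1], b[2]), "")
  switch(spec$spectral_mode,
    absolute = stats::setNames(seq_along(band_names), paste0("abs_", band_names)),
    relative = stats::setNames(seq_along(band_names), paste0("rel_", band_names)),
    both = stats::setNames(seq_len(2 * length(band_names)),
                           c(paste0("abs_", band_names),
                             paste0("rel_", band_names))))
}

#' Feature-level transposition augmentation
#'
#' Applies to a featurized epoch frame the exact column transform that
#' recording-level channel transposition induces: asymmetry columns are
#' negated under a left-right flip, and per-channel spectral/RQA
#' columns (and asymmetry pair blocks) are permuted by the derivation
#' map. Equivalent to re-featurizing [augment_transpositions()] output,
#' at no signal-processing cost.
#'
#' @param feats featurized `"epoch_frame"`.
#' @param montage the [montage_spec()].
#' @param which one of `"lr"`, `"fb"`, `"lrfb"`.
#' @return The transformed epoch frame.
#' @export
augment_features <- function(feats, montage, which = c("lr", "fb", "lrfb")) {
  which <- match.arg(which)
  schema <- attr(feats, "schema")
  cols <- attr(feats, "feature_names")
  map <- switch(which,
                lr = montage$left_right_map,
                fb = montage$front_back_map,
                lrfb = montage$left_right_map[montage$front_back_map])
  fmat <- as.matrix(feats[, cols, drop = FALSE])
  new <- fmat
  ## per-channel blocks permute: new channel lab gets old channel map[lab]
  for (fam in c("spectral", "rqa")) {
    for (ci in seq_along(montage$labels)) {
      dst <- schema$family == fam & schema$channel == montage$labels[ci]
      src <- schema$family == fam & schema$channel == montage$labels[map[ci]]
      new[, cols[dst]] <- fmat[, cols[src]]
    }
  }
  ## asymmetry blocks: pair (l, r) maps to pair containing (map[l], map[r])
  pair_key <- function(p) paste0(montage$labels[p[1]], "|", montage$labels[p[2]])
  for (p in montage$left_right_pairs) {
    dst <- schema$family == "asym" & schema$channel == pair_key(p)
    mapped <- c(map[p[1]], map[p[2]])
    flipped <- FALSE
    src_pair <- NULL
    for (q in montage$left_right_pairs) {
      if (identical(as.integer(mapped), as.integer(q))) { src_pair <- q; flipped <- FALSE }
      if (identical(as.integer(rev(mapped)), as.integer(q))) { src_pair <- q; flipped <- TRUE }
    }
    if (is.null(src_pair)) stop("transposition map does not preserve pairs")
    src <- schema$family == "asym" & schema$channel == pair_key(src_pair)
    ## asym(L,R) computed from source pair: if the map sends our (L,R) to
    ## the source's (R,L) order, the index negates.
    new[, cols[dst]] <- if (flipped) -fmat[, cols[src]] else fmat[, cols[src]]
  }
  feats[, cols] <- new
  feats
}
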