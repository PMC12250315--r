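#' Bipolar montage specification
#'
#' Describes how referential channels are combined into bipolar
#' derivations, which derivations form homologous left/right pairs, and
#' how derivation indices permute under the two transposition axes used
#' for training-data augmentation. Both maps must be involutions
#' (applying twice restores the original order).
#'
#' @param derivations list of `c(anode, cathode)` label pairs, in output
#'   order.
#' @param left_right_pairs list of `c(left_index, right_index)` pairs of
#'   derivation indices; every derivation appears in at most one pair.
#' @param left_right_map,front_back_map integer permutations of
#'   derivation indices realizing the left-right and frontal-occipital
#'   channel transpositions.
#' @return An object of class `"montage_spec"`.
#' @export
montage_spec <- function(derivations, left_right_pairs,
                         left_right_map, front_back_map) {
  n <- length(derivations)
  chk_inv <- function(m, what) {
    if (!identical(sort(m), seq_len(n)) || !identical(m[m], seq_len(n)))
      stop(what, " must be an involutive permutation of 1..", n)
  }
  chk_inv(as.integer(left_right_map), "left_right_map")
  chk_inv(as.integer(front_back_map), "front_back_map")
  idx <- unlist(left_right_pairs)
  if (anyDuplicated(idx))
    stop("a derivation appears in more than one left/right pair")
  labs <- vapply(derivations, function(d) paste(d, collapse = "-"), "")
  if (anyDuplicated(labs)) stop("duplicate derivations: ",
                                paste(labs[duplicated(labs)], collapse = ", "))
  structure(list(derivations = derivations,
                 labels = labs,
                 left_right_pairs = left_right_pairs,
                 left_right_map = as.integer(left_right_map),
                 front_back_map = as.integer(front_back_map),
                 midline = setdiff(seq_len(n), idx)),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec>", length(x$labels), "derivations:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Default longitudinal bipolar montage for the synthetic 10-20 subset
#'
#' For the 8-electrode generator layout (F3/F4, C3/C4, O1/O2, T3/T4)
#' this is a reduced double-banana: two anterior-posterior chains per
#' hemisphere (F-C-O parasagittal and F-T-O temporal), giving 8
#' derivations in 4 homologous pairs. The frontal-occipital map swaps
#' the front and back derivation of each chain; the left-right map
#' swaps hemispheres.
#'
#' @param channel_labels electrode labels present in the recording.
#' @return A [montage_spec()].
#' @export
default_montage <- function(channel_labels = synth_channel_labels(8)) {
  need <- c("F3", "C3", "O1", "T3", "F4", "C4", "O2", "T4")
  if (!all(need %in% channel_labels))
    stop("default_montage requires electrodes ",
         paste(setdiff(need, channel_labels), collapse = ", "))
  derivs <- list(c("F3", "C3"), c("C3", "O1"), c("F3", "T3"), c("T3", "O1"),
                 c("F4", "C4"), c("C4", "O2"), c("F4", "T4"), c("T4", "O2"))
  montage_spec(
    derivations = derivs,
    left_right_pairs = list(c(1L, 5L), c(2L, 6L), c(3L, 7L), c(4L, 8L)),
    left_right_map = c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L),
    front_back_map = c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L))
}

#' Derive a bipolar montage from a referential recording
#'
#' Output channel i is `anode_i - cathode_i` sample-wise; labels become
#' `"A-C"` strings in the spec's order.
#'
#' @param rec an [recording()] holding referential channels.
#' @param spec a [montage_spec()].
#' @return A new [recording()] with one channel per derivation.
#' @export
derive_bipolar_montage <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "montage_spec"))
  for (d in spec$derivations) {
    missing <- setdiff(d, rec$channel_labels)
    if (length(missing))
      stop("montage references absent channel(s): ",
           paste(missing, collapse = ", "))
  }
  sig <- t(vapply(spec$derivations, function(d)
    rec$signal[match(d[1], rec$channel_labels), ] -
      rec$signal[match(d[2], rec$channel_labels), ],
    numeric(ncol(rec$signal))))
  recording(sig, rec$fs, spec$labels, rec$subject_id, rec$start_time_s)
}

#' Channel-transposition augmentations of a montaged recording
#'
#' Returns the left-right-flipped, front-back-flipped and doubly
#' flipped copies of a montaged recording. Each copy is a pure row
#' permutation of the input signal (row i of a copy holds the signal of
#' derivation `map[i]`), with channel labels unchanged, so downstream
#' features of a copy are a fixed column transform of the original's.
#' Intended for training folds only.
#'
#' @param rec a montaged [recording()] whose channels follow `spec`.
#' @param spec the [montage_spec()].
#' @return Named list of three recordings: `lr`, `fb`, `lrfb`.
#' @export
augment_transpositions <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "montage_spec"))
  if (!identical(rec$channel_labels, spec$labels))
    stop("recording channels do not match the montage derivations")
  permute <- function(map) {
    out <- rec
    out$signal <- rec$signal[map, , drop = FALSE]
    rownames(out$signal) <- rec$channel_labels
    out
  }
  list(lr = permute(spec$left_right_map),
       fb = permute(spec$front_back_map),
       lrfb = permute(spec$left_right_map[spec$front_back_map]))
}

#' Read/write a montage spec as YAML
#' @param spec a [montage_spec()]; `path` a file path.
#' @return `read_montage_yaml` returns a [montage_spec()].
#' @rdname montage_yaml
#' @export
write_montage_yaml <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML montage files")
  yaml::write_yaml(list(
    derivations = lapply(spec$derivations, as.character),
    left_right_pairs = lapply(spec$left_right_pairs, as.integer),
    left_right_map = spec$left_right_map,
    front_back_map = spec$front_back_map), path)
  invisible(path)
}

#' @param path YAML file path.
#' @rdname montage_yaml
#' @export
read_montage_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML montage files")
  y <- yaml::read_yaml(path)
  montage_spec(y$derivations, y$left_right_pairs,
               unlist(y$left_right_map), unlist(y$front_back_map))
}
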