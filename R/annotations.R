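#' Multi-rater seizure annotations
#'
#' Per-rater binary seizure masks at 1 Hz resolution. Second `j` (the
#' half-open interval `[j, j+1)` from record start) is marked 1 when the
#' rater considers it seizure. Event lists are derived from masks, never
#' stored as primary data.
#'
#' @param masks integer/logical matrix, raters x seconds.
#' @return An object of class `"annotation_set"`.
#' @export
annotation_set <- function(masks) {
  masks <- as.matrix(masks) * 1L
  if (!all(masks %in% c(0L, 1L))) stop("masks must be binary")
  structure(list(masks = masks, raters = nrow(masks),
                 duration_s = ncol(masks)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d raters x %d s; marked seconds per rater: %s\n",
              x$raters, x$duration_s,
              paste(rowSums(x$masks), collapse = ", ")))
  invisible(x)
}

## 1 Hz mask from a half-open event list: second j is marked iff
## [j, j+1) intersects some event.
mask_from_events <- function(events, nsec) {
  m <- integer(nsec)
  if (nrow(events) == 0L) return(m)
  for (e in seq_len(nrow(events))) {
    j0 <- max(0L, floor(events$onset_s[e]))
    j1 <- min(nsec - 1L, ceiling(events$offset_s[e]) - 1L)
    if (j1 >= j0) {
      js <- j0:j1
      hit <- js < events$offset_s[e] & (js + 1) > events$onset_s[e]
      m[js[hit] + 1L] <- 1L
    }
  }
  m
}

## Maximal runs of 1s in a binary vector -> half-open second intervals.
mask_to_events <- function(mask) {
  r <- rle(as.integer(mask) > 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  events_df(onset_s = starts[keep], offset_s = ends[keep])
}

#' Consensus seizure events
#'
#' Maximal runs of seconds during which at least `k` raters mark
#' seizure, returned as a sorted, non-overlapping half-open event list.
#' Antitone in `k`: events at `k+1` are contained in events at `k`.
#'
#' @param ann an [annotation_set()].
#' @param k consensus threshold, `1 <= k <= raters`.
#' @return data.frame with columns `onset_s`, `offset_s` (seconds).
#' @export
consensus_events <- function(ann, k = 2L) {
  stopifnot(inherits(ann, "annotation_set"))
  if (k < 1L || k > ann$raters)
    stop("k must lie in 1..", ann$raters)
  mask_to_events(colSums(ann$masks) >= k)
}

## Per-rater event table for the sidecar CSV.
annotation_events_table <- function(ann, subject) {
  rows <- list()
  for (r in seq_len(ann$raters)) {
    ev <- mask_to_events(ann$masks[r, ])
    if (nrow(ev))
      rows[[r]] <- data.frame(subject = subject, rater = r,
                              onset_s = ev$onset_s, offset_s = ev$offset_s)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), rater = integer(0),
               onset_s = numeric(0), offset_s = numeric(0))
}

#' Read a sidecar annotation CSV into per-subject annotation sets
#'
#' @param path CSV with columns subject, rater, onset_s, offset_s.
#' @param duration_s named numeric vector of record durations in seconds,
#'   names are subject ids.
#' @param n_raters number of raters (raters absent from the file for a
#'   subject contribute all-zero masks).
#' @return Named list of [annotation_set()] objects.
#' @export
read_annotations_csv <- function(path, duration_s, n_raters) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (id in names(duration_s)) {
    nsec <- ceiling(duration_s[[id]])
    masks <- matrix(0L, n_raters, nsec)
    sub <- df[df$subject == id, , drop = FALSE]
    if (nrow(sub)) for (i in seq_len(nrow(sub))) {
      r <- sub$rater[i]
      masks[r, ] <- masks[r, ] |
        mask_from_events(events_df(sub$onset_s[i], sub$offset_s[i]), nsec)
    }
    out[[id]] <- annotation_set(masks * 1L)
  }
  out
}
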