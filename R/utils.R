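`%||%` <- function(a, b) if (is.null(a)) b else a

## Half-open interval convention [a, b): does [a1,b1) intersect [a2,b2)?
intervals_overlap <- function(a1, b1, a2, b2) a1 < b2 & a2 < b1

## Is [a1,b1) fully inside [a2,b2)?
interval_inside <- function(a1, b1, a2, b2) a1 >= a2 & b1 <= b2

## Event lists are data.frames with onset_s / offset_s columns, half-open.
events_df <- function(onset_s = numeric(0), offset_s = numeric(0)) {
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s))
  if (any(ev$offset_s <= ev$onset_s)) stop("events must have offset_s > onset_s")
  ev[order(ev$onset_s), , drop = FALSE]
}

check_events <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(events_df())
  stopifnot(all(c("onset_s", "offset_s") %in% names(events)))
  ev <- events[order(events$onset_s), , drop = FALSE]
  if (nrow(ev) > 1 && any(ev$onset_s[-1] < ev$offset_s[-nrow(ev)]))
    stop("events overlap; merge them first (see merge_close_seizures)")
  rownames(ev) <- NULL
  ev
}

## Union of half-open intervals given by sorted starts (merges overlaps
## and adjacencies; drops empties).
merge_intervals <- function(lo, hi) {
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  o <- order(lo); lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= out_hi[length(out_hi)]) {
      out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[k])
    } else {
      out_lo <- c(out_lo, lo[k]); out_hi <- c(out_hi, hi[k])
    }
  }
  data.frame(lo = out_lo, hi = out_hi)
}

## Derive a per-call RNG seed from a base seed and a stream index,
## staying inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}
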