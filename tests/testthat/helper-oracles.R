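# Independent brute-force oracles shared by module and acceptance tests.

# Independent per-second brute-force labeler used as the oracle for the
# interval-logic implementation.
brute_label_seconds <- function(dur, events, pre_start = 360, pre_end = 60,
                                post_buf = 60) {
  state <- rep("excluded", dur)
  for (s in seq_len(dur) - 1) {
    ict <- pre <- FALSE
    inter_ok <- TRUE
    if (nrow(events)) {
      for (e in seq_len(nrow(events))) {
        on <- events$onset_s[e]; off <- events$offset_s[e]
        if (s >= on && s < off) ict <- TRUE
        if (s >= on - pre_start && s < on - pre_end) pre <- TRUE
        ## second is interictal-eligible only if clear of every event's
        ## preictal reach and post-seizure buffer
        if (s >= on - pre_start && s < off + post_buf) inter_ok <- FALSE
      }
    }
    state[s + 1] <- if (ict) "ictal" else if (pre) "preictal" else
      if (inter_ok) "interictal" else "excluded"
  }
  state
}

brute_epoch_label <- function(dur, events, len = 20, ...) {
  sec <- brute_label_seconds(dur, events, ...)
  n_ep <- floor(dur / len)
  vapply(seq_len(n_ep), function(i) {
    block <- sec[((i - 1) * len + 1):(i * len)]
    if (any(block == "ictal")) return("ictal")
    u <- unique(block)
    if (length(u) == 1 && u %in% c("preictal", "interictal")) return(u)
    "excluded"
  }, "")
}

random_events <- function(dur, max_n = 3) {
  n <- sample(0:max_n, 1)
  if (n == 0) return(seizecast:::events_df())
  repeat {
    on <- sort(sample.int(dur - 60, n))
    d <- sample(20:120, n, replace = TRUE)
    off <- pmin(on + d, dur)
    if (all(on[-1] > off[-n])) return(seizecast:::events_df(on, off))
  }
}


# Independent per-epoch brute-force alarm/state simulator. Walks the
# epoch grid with an explicit state machine, classifies each alarm and
# counts every quantity by direct looping.
brute_alarm <- function(probs, times, len, events, sph, sop, thr,
                        censor = rep(FALSE, length(times))) {
  n <- length(times)
  state <- rep("none", n)
  trig <- numeric(0); outc <- character(0)
  active_until <- -Inf
  for (i in seq_len(n)) {
    if (probs[i] > thr && times[i] >= active_until) {
      t0 <- times[i]
      tp <- FALSE
      if (nrow(events)) for (e in seq_len(nrow(events)))
        if (events$onset_s[e] >= t0 + sph && events$onset_s[e] < t0 + sph + sop)
          tp <- TRUE
      trig <- c(trig, t0); outc <- c(outc, if (tp) "true_positive" else "false_positive")
      active_until <- t0 + sph + sop
    }
  }
  for (a in seq_along(trig))
    for (i in seq_len(n))
      if (times[i] >= trig[a] && times[i] < trig[a] + sph + sop)
        state[i] <- if (outc[a] == "true_positive") "true_alarm" else "false_alarm"
  missed <- c()
  if (nrow(events)) for (e in seq_len(nrow(events))) {
    cov <- FALSE
    for (a in seq_along(trig))
      if (events$onset_s[e] >= trig[a] + sph &&
          events$onset_s[e] < trig[a] + sph + sop) cov <- TRUE
    if (!cov) missed <- c(missed, events$onset_s[e])
  }
  keep <- !censor
  miss_time <- 0
  for (on in missed)
    for (i in which(keep))
      if (times[i] >= on - sph - sop && times[i] < on - sph)
        miss_time <- miss_time + len
  list(trigger_s = trig, outcome = outc, state = state,
       fn_count = length(missed),
       tp_time = sum(state[keep] == "true_alarm") * len,
       fp_time = sum(state[keep] == "false_alarm") * len,
       tn_time = sum(state[keep] == "none") * len,
       miss_time = miss_time,
       n_fp_alarms = sum(outc == "false_positive"))
}

random_alarm_instance <- function() {
  n <- sample(60:150, 1)
  len <- 20
  times <- (seq_len(n) - 1) * len
  probs <- pmin(1, pmax(0, stats::runif(n)^sample(c(1, 2, 0.5), 1)))
  dur <- n * len
  n_ev <- sample(0:3, 1)
  events <- if (n_ev > 0) {
    on <- sort(sample.int(dur - 80, n_ev))
    off <- pmin(on + sample(30:120, n_ev, TRUE), dur)
    if (n_ev > 1) off[-n_ev] <- pmin(off[-n_ev], on[-1])  # keep disjoint
    seizecast:::events_df(on, off)
  } else seizecast:::events_df()
  sph <- sample(c(0, 60, 180, 360), 1)
  sop <- sample(c(60, 120, 300, 420), 1)
  list(trace = manual_trace(probs, record_end = dur),
       events = merge_close_seizures(events, sph),
       sph = sph, sop = sop, thr = stats::runif(1))
}


# Brute-force recurrence oracle on a short trajectory: explicit loops
# over the recurrence matrix and its diagonal/vertical lines.
brute_rqa <- function(x, m = 3, tau = 1, eps_frac = 0.2, lmin = 2) {
  npt <- length(x) - (m - 1) * tau
  emb <- sapply(1:m, function(k) x[(1:npt) + (k - 1) * tau])
  eps <- eps_frac * stats::sd(x)
  R <- matrix(FALSE, npt, npt)
  for (i in 1:npt) for (j in 1:npt)
    if (i != j && sqrt(sum((emb[i, ] - emb[j, ])^2)) <= eps) R[i, j] <- TRUE
  n_rec <- sum(R)
  lines_of <- function(get) {
    lens <- c()
    for (g in seq_len(2 * npt - 1)) {
      run <- 0
      for (cell in get(g)) {
        if (!is.na(cell) && cell) run <- run + 1
        else { if (run > 0) lens <- c(lens, run); run <- 0 }
      }
      if (run > 0) lens <- c(lens, run)
    }
    lens
  }
  diag_cells <- function(g) {                # g indexes offsets -(npt-1)..(npt-1), 0 skipped
    d <- g - npt
    if (d == 0) return(logical(0))
    i <- max(1, 1 - d):min(npt, npt - d)
    R[cbind(i, i + d)]
  }
  vert_cells <- function(g) if (g <= npt) R[, g] else logical(0)
  dl <- lines_of(diag_cells); vl <- lines_of(vert_cells)
  dl_long <- dl[dl >= lmin]; vl_long <- vl[vl >= lmin]
  c(RR = n_rec / (npt * (npt - 1)),
    DET = if (n_rec) sum(dl_long) / n_rec else 0,
    LAM = if (n_rec) sum(vl_long) / n_rec else 0,
    L = if (length(dl_long)) mean(dl_long) else 0)
}

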