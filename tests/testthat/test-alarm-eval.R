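test_that("alarm raising and tallies match the brute-force simulator exactly", {
  set.seed(500)
  for (rep in 1:500) {
    inst <- random_alarm_instance()
    cfg <- alarm_config(inst$sph, inst$sop, inst$thr)
    trk <- raise_alarms(inst$trace, cfg, inst$events)
    tl <- tally(trk)
    ref <- brute_alarm(inst$trace$preictal_prob, inst$trace$epoch_start_s,
                       20, inst$events, inst$sph, inst$sop, inst$thr)
    lbl <- sprintf("rep %d", rep)
    expect_equal(trk$alarms$trigger_s, ref$trigger_s, label = lbl)
    expect_equal(trk$alarms$outcome, ref$outcome, label = lbl)
    expect_identical(trk$state, ref$state, label = lbl)
    expect_equal(tl$fn_count, ref$fn_count, label = lbl)
    expect_equal(tl$tp_time_s, ref$tp_time, label = lbl)
    expect_equal(tl$fp_time_s, ref$fp_time, label = lbl)
    expect_equal(tl$tn_time_s, ref$tn_time, label = lbl)
    expect_equal(tl$miss_time_s, ref$miss_time, label = lbl)
    expect_equal(tl$n_fp_alarms, ref$n_fp_alarms, label = lbl)
  }
})

test_that("alarm outcomes follow the warning-window rule", {
  ## single spike at t = 700 s over a 2000 s record
  probs <- rep(0, 100); probs[36] <- 0.9          # epoch starting 700 s
  tr <- manual_trace(probs)
  ev <- seizecast:::events_df(1000, 1060)
  tp <- raise_alarms(tr, alarm_config(180, 300, 0.5), ev)
  expect_equal(tp$alarms$outcome, "true_positive") # warning [880, 1180)
  expect_equal(nrow(tp$fn_events), 0L)
  fp <- raise_alarms(tr, alarm_config(360, 300, 0.5), ev)
  expect_equal(fp$alarms$outcome, "false_positive") # warning [1060, 1360)
  expect_equal(nrow(fp$fn_events), 1L)
  ## constant zero probability: no alarms, all seizures missed
  none <- raise_alarms(manual_trace(rep(0, 100)), alarm_config(60, 300, 0.5), ev)
  expect_equal(nrow(none$alarms), 0L)
  expect_equal(tally(none)$fn_count, 1L)
  expect_error(alarm_config(60, 300, 1.5), "threshold")
  expect_error(alarm_config(-1, 300, 0.5), "sph")
})

test_that("enlarging the SOP never flips a true positive to false positive", {
  set.seed(501)
  for (rep in 1:50) {
    inst <- random_alarm_instance()
    trk <- raise_alarms(inst$trace, alarm_config(inst$sph, inst$sop, inst$thr),
                        inst$events)
    if (!nrow(trk$alarms)) next
    bigger <- inst$sop + 120
    for (a in seq_len(nrow(trk$alarms))) {
      t0 <- trk$alarms$trigger_s[a]
      out2 <- if (nrow(inst$events) &&
                  any(inst$events$onset_s >= t0 + inst$sph &
                      inst$events$onset_s < t0 + inst$sph + bigger))
        "true_positive" else "false_positive"
      if (trk$alarms$outcome[a] == "true_positive")
        expect_equal(out2, "true_positive")
    }
  }
})

test_that("sensitivity handles full credit, a half-credit fixture and no seizures", {
  ## all seizures covered: sensitivity 1
  probs <- rep(0, 100); probs[c(16, 60)] <- 1     # epochs at 300 s, 1180 s
  ev <- seizecast:::events_df(c(400, 1300), c(440, 1340))
  tl <- tally(raise_alarms(manual_trace(probs), alarm_config(0, 200, 0.5), ev))
  expect_equal(sensitivity(tl), 1)
  expect_equal(tl$fn_count, 0L)
  ## hand-counted half credit: one covered seizure (alarm span 200 s =
  ## 10 epochs), one missed (hypothetical window 200 s = 10 epochs)
  probs2 <- rep(0, 150); probs2[21] <- 1          # epoch at 400 s
  ev2 <- seizecast:::events_df(c(500, 2000), c(540, 2040))
  tl2 <- tally(raise_alarms(manual_trace(probs2), alarm_config(0, 200, 0.5), ev2))
  expect_equal(tl2$tp_time_s, 200)
  expect_equal(tl2$miss_time_s, 200)
  expect_equal(sensitivity(tl2), 0.5)
  ## no seizures and no alarms: undefined, reported missing
  tl3 <- tally(raise_alarms(manual_trace(rep(0, 50)),
                            alarm_config(60, 300, 0.5),
                            seizecast:::events_df()))
  expect_true(is.na(sensitivity(tl3)))
})

test_that("corrected TIW matches its closed forms and fixture", {
  mk_tally <- function(tp, fp, true_alarm, total) {
    structure(list(tp_time_s = tp, fp_time_s = fp,
                   tn_time_s = total - tp - fp, fn_count = 0L,
                   miss_time_s = 0, time_in_true_alarm_s = true_alarm,
                   total_time_s = total, n_alarms = 0L, n_fp_alarms = 0L,
                   n_seizures = 0L), class = "confusion_tally")
  }
  expect_equal(corrected_tiw(mk_tally(0, 0, 0, 3600)), 0)
  expect_equal(corrected_tiw(mk_tally(0, 3600, 0, 3600)), 1)
  ## 600 s of alarms of which 300 s true, over 3600 s
  expect_equal(corrected_tiw(mk_tally(300, 300, 300, 3600)), 1 / 11)
  expect_error(corrected_tiw(mk_tally(3600, 0, 3600, 3600)), "degenerate")
  ## via the alarm machinery: all alarm time true -> 0
  probs <- rep(0, 100); probs[16] <- 1
  ev <- seizecast:::events_df(400, 440)
  tl <- tally(raise_alarms(manual_trace(probs), alarm_config(0, 200, 0.5), ev))
  expect_equal(corrected_tiw(tl), 0)
})

test_that("false detection rate counts FP alarms per evaluable hour", {
  ## two isolated spikes far from any seizure over 2 h
  probs <- rep(0, 360); probs[c(50, 200)] <- 1
  trk <- raise_alarms(manual_trace(probs), alarm_config(60, 300, 0.5),
                      seizecast:::events_df())
  expect_equal(fdr_per_hour(trk), 1)
  expect_equal(fdr_per_hour(raise_alarms(manual_trace(rep(0, 360)),
                                         alarm_config(60, 300, 0.5),
                                         seizecast:::events_df())), 0)
  set.seed(502)
  for (rep in 1:20) {
    inst <- random_alarm_instance()
    trk <- raise_alarms(inst$trace, alarm_config(inst$sph, inst$sop, inst$thr),
                        inst$events)
    ref <- brute_alarm(inst$trace$preictal_prob, inst$trace$epoch_start_s, 20,
                       inst$events, inst$sph, inst$sop, inst$thr)
    hours <- length(inst$trace$preictal_prob) * 20 / 3600
    expect_equal(fdr_per_hour(trk), ref$n_fp_alarms / hours)
  }
})

test_that("threshold sweeps recover perfect, reversed and random regimes", {
  ## perfectly separating trace: high probability exactly so that each
  ## alarm covers its seizure, zero elsewhere
  probs <- rep(0, 200); probs[c(26, 101)] <- 1
  ev <- list(S01 = seizecast:::events_df(c(600, 2100), c(660, 2160)))
  tr <- manual_trace(probs)
  sw <- threshold_sweep(list(tr), ev, sph_s = 0, sop_s = 200)
  expect_equal(sw$auroc, 1)
  expect_equal(sw$auprc, 1)
  expect_gt(sw$baseline_auprc, 0)
  ## degenerate constant trace: flagged, AUROC 0.5
  sw_const <- threshold_sweep(list(manual_trace(rep(0.3, 200))), ev,
                              sph_s = 0, sop_s = 200)
  expect_true(sw_const$degenerate)
  expect_equal(sw_const$auroc, 0.5)
  ## label-independent random trace at SPH 0 (where true-alarm and
  ## missed-seizure credit windows have equal length): AUROC near 1/2
  set.seed(77)
  tr_rand <- manual_trace(stats::runif(600))
  ev_r <- list(S01 = seizecast:::events_df(c(2000, 6000, 10000),
                                           c(2060, 6060, 10060)))
  sw_rand <- threshold_sweep(list(tr_rand), ev_r, sph_s = 0, sop_s = 300)
  expect_lt(abs(sw_rand$auroc - 0.5), 0.2)
  expect_lt(abs(sw_rand$auprc - sw_rand$baseline_auprc), 0.15)
})

test_that("scoring with pre-merged events equals merging inside the sweep", {
  set.seed(503)
  probs <- stats::runif(200)
  ev_raw <- seizecast:::events_df(c(500, 700, 2500), c(560, 760, 2560))
  tr <- manual_trace(probs)
  sph <- 180
  merged <- merge_close_seizures(ev_raw, sph)
  expect_equal(nrow(merged), 2L)
  trk_a <- raise_alarms(tr, alarm_config(sph, 300, 0.5), merged)
  trk_b <- raise_alarms(tr, alarm_config(sph, 300, 0.5),
                        merge_close_seizures(merged, sph))
  expect_identical(tally(trk_a), tally(trk_b))
})

test_that("grid sweep emits one row per cell with order-invariant pooling", {
  set.seed(504)
  mk <- function(id) manual_trace(stats::runif(120), subject = id)
  traces <- list(S01 = mk("S01"), S02 = mk("S02"))
  ev <- list(S01 = seizecast:::events_df(1000, 1080),
             S02 = seizecast:::events_df())
  g <- grid_sweep(traces, ev, sph_grid = c(60, 120), sop_grid = c(60, 180),
                  n_thresholds = 11)
  expect_equal(nrow(g), 4L)
  expect_true(all(c("auroc", "auprc", "tiw_at_target") %in% names(g)))
  g_rev <- grid_sweep(rev(traces), ev, sph_grid = c(60, 120),
                      sop_grid = c(60, 180), n_thresholds = 11)
  expect_equal(g$auroc, g_rev$auroc)
  expect_equal(g$tiw_at_target, g_rev$tiw_at_target)
})
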