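test_that("background generation has the right shape, seeding and spectrum", {
  cfg <- synth_config(n_subjects = 1, record_duration = 3600, fs = 40,
                      n_channels = 8, seed = 5)
  rec <- generate_background(cfg, 1)
  expect_equal(dim(rec$signal), c(8L, 144000L))
  expect_identical(rec$channel_labels,
                   c("F3", "F4", "C3", "C4", "O1", "O2", "T3", "T4"))

  rec2 <- generate_background(cfg, 1)
  expect_identical(rec$signal, rec2$signal)
  rec3 <- generate_background(cfg, 2)
  expect_false(identical(rec$signal, rec3$signal))

  ## independent periodogram oracle: mean band power decreasing over
  ## the conventional bands
  x <- rec$signal[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 40), plot = FALSE,
                          taper = 0, detrend = TRUE)
  bp <- vapply(list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 20)), function(b)
    mean(sp$spec[sp$freq >= b[1] & sp$freq < b[2]]), 0)
  expect_true(all(diff(bp) < 0))
})

test_that("homologous channel pairs are more correlated than non-pairs", {
  cfg <- synth_config(n_subjects = 1, record_duration = 600, seed = 2)
  rec <- generate_background(cfg, 1)
  cm <- stats::cor(t(rec$signal))
  pair_cor <- mean(c(cm["F3", "F4"], cm["C3", "C4"], cm["O1", "O2"],
                     cm["T3", "T4"]))
  nonpair_cor <- mean(c(cm["F3", "C4"], cm["C3", "O2"], cm["O1", "T4"],
                        cm["F3", "O2"]))
  expect_gt(pair_cor, nonpair_cor + 0.1)
})

test_that("config validation rejects degenerate cohorts", {
  expect_error(synth_config(n_channels = 7), "even")
  expect_error(synth_config(record_duration = 0), "positive")
  expect_error(synth_config(fs = 20), "40")
  expect_error(synth_config(preictal_strength = -1), ">= 0")
})

test_that("seizure injection yields sorted non-overlapping events that fit", {
  cfg <- synth_config(n_subjects = 1, record_duration = 3600,
                      seizures_min = 3, seizures_max = 3, seed = 9)
  rec <- generate_background(cfg, 1)
  inj <- inject_seizures(rec, cfg, 1)
  ev <- inj$truth$seizure_events
  expect_equal(nrow(ev), 3L)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_true(all(ev$onset_s[-1] - ev$offset_s[-3] >= 360))
  expect_true(all(ev$offset_s <= 3600))
  ## planted window bookkeeping: ends at onset, spans <= preictal_span
  w <- inj$truth$planted_preictal_windows
  expect_equal(w$end_s, ev$onset_s)
  expect_true(all(w$end_s - w$start_s <= cfg$preictal_span_s))

  ## too many seizures for the record errors informatively
  cfg_bad <- synth_config(n_subjects = 1, record_duration = 900,
                          seizures_min = 5, seizures_max = 5, seed = 9)
  rec_b <- generate_background(cfg_bad, 1)
  expect_error(inject_seizures(rec_b, cfg_bad, 1), "cannot place")
})

test_that("planted preictal signature shifts 8-20 Hz power; absent at strength 0", {
  ## independent periodogram (spec.pgram) on planted vs matched windows
  rel_power_8_20 <- function(x, fs) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0, detrend = TRUE)
    sum(sp$spec[sp$freq >= 8 & sp$freq < 20]) /
      sum(sp$spec[sp$freq >= 0.5 & sp$freq < 20])
  }
  run_cohort <- function(strength, n = 25) {
    diffs <- numeric(n)
    cfg <- synth_config(n_subjects = n, record_duration = 1800,
                        seizures_min = 1, seizures_max = 1,
                        preictal_strength = strength, seed = 31)
    for (i in seq_len(n)) {
      rec <- generate_background(cfg, i)
      inj <- inject_seizures(rec, cfg, i)
      ev <- inj$truth$seizure_events
      w <- inj$truth$planted_preictal_windows
      fs <- cfg$fs
      win <- function(a, b) inj$recording$signal[1, (round(a * fs) + 1):round(b * fs)]
      ## matched interictal window: same length, ending 400 s before onset
      m_end <- w$start_s[1] - 100
      if (m_end - (w$end_s[1] - w$start_s[1]) < 0) { diffs[i] <- NA; next }
      diffs[i] <- rel_power_8_20(win(w$start_s[1], w$end_s[1]), fs) -
        rel_power_8_20(win(m_end - (w$end_s[1] - w$start_s[1]), m_end), fs)
    }
    diffs[is.finite(diffs)]
  }
  d2 <- run_cohort(2)
  expect_lt(stats::wilcox.test(d2, alternative = "greater")$p.value, 0.01)
  d0 <- run_cohort(0)
  expect_gt(stats::wilcox.test(d0, alternative = "greater")$p.value, 0.05)
})

test_that("interictal and planted-window variance are exchangeable at strength 0", {
  cfg <- synth_config(n_subjects = 20, record_duration = 1800,
                      seizures_min = 1, seizures_max = 1,
                      preictal_strength = 0, seed = 17)
  ratio <- numeric(20)
  for (i in 1:20) {
    inj <- inject_seizures(generate_background(cfg, i), cfg, i)
    w <- inj$truth$planted_preictal_windows
    fs <- cfg$fs
    pre <- inj$recording$signal[1, (round(w$start_s[1] * fs) + 1):round(w$end_s[1] * fs)]
    len <- length(pre)
    m_end <- round((w$start_s[1] - 100) * fs)
    if (m_end - len < 1) { ratio[i] <- NA; next }
    inter <- inj$recording$signal[1, (m_end - len + 1):m_end]
    ratio[i] <- stats::var(pre) / stats::var(inter)
  }
  expect_lt(abs(mean(ratio, na.rm = TRUE) - 1), 0.05)
})

test_that("annotations reproduce truth at zero jitter and bound overlap at 5 s", {
  cfg0 <- synth_config(n_subjects = 1, record_duration = 1800,
                       rater_noise_s = 0, seizures_min = 2, seizures_max = 2,
                       seed = 13)
  inj <- inject_seizures(generate_background(cfg0, 1), cfg0, 1)
  ann <- synth_annotations(inj$truth, cfg0, 1800, 1)
  truth_mask <- seizecast:::mask_from_events(inj$truth$seizure_events, 1800)
  for (r in 1:3) expect_identical(ann$masks[r, ], truth_mask)
  expect_identical(consensus_events(ann, 3), inj$truth$seizure_events)

  cfg5 <- synth_config(n_subjects = 1, record_duration = 1800,
                       rater_noise_s = 5, seizures_min = 2, seizures_max = 2,
                       seed = 13)
  ann5 <- synth_annotations(inj$truth, cfg5, 1800, 1)
  for (r in 1:3) {
    ev_r <- seizecast:::mask_to_events(ann5$masks[r, ])
    for (e in seq_len(nrow(inj$truth$seizure_events))) {
      tru <- inj$truth$seizure_events[e, ]
      overlap <- max(0, min(tru$offset_s, ev_r$offset_s[e]) -
                        max(tru$onset_s, ev_r$onset_s[e]))
      expect_gte(overlap, (tru$offset_s - tru$onset_s) - 10)
    }
  }
})

test_that("single-rater annotation sets work downstream with k = 1", {
  cfg <- synth_config(n_subjects = 1, n_raters = 1, record_duration = 1200,
                      rater_noise_s = 0, seizures_min = 1, seizures_max = 1,
                      seed = 3)
  inj <- inject_seizures(generate_background(cfg, 1), cfg, 1)
  ann <- synth_annotations(inj$truth, cfg, 1200, 1)
  expect_equal(ann$raters, 1L)
  expect_identical(consensus_events(ann, 1), inj$truth$seizure_events)
  expect_error(consensus_events(ann, 2), "1..1")
})

test_that("cohort simulation is reproducible and honors the seizure fraction", {
  cfg <- synth_config(n_subjects = 4, record_duration = 1200,
                      seizures_min = 1, seizures_max = 2,
                      seizure_subject_fraction = 0.5, seed = 23)
  co <- simulate_cohort(cfg)
  expect_length(co, 4L)
  has <- vapply(co, `[[`, TRUE, "has_seizure")
  expect_equal(sum(has), 2L)
  expect_true(all(vapply(co[has], function(s) nrow(s$truth$seizure_events) > 0, TRUE)))
  expect_true(all(vapply(co[!has], function(s) nrow(s$truth$seizure_events) == 0, TRUE)))
  co2 <- simulate_cohort(cfg)
  expect_identical(co[[1]]$recording$signal, co2[[1]]$recording$signal)
  expect_identical(co[[2]]$annotations$masks, co2[[2]]$annotations$masks)
})
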