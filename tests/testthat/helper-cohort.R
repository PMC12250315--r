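# Full end-to-end cohort runs (generation -> preprocessing -> features
# -> nested CV), cached per planted-signature strength so the
# signal-recovery, null-control and leakage tests share one computation.

cohort_run <- function(strength, gen_seed = 1L, cv_seed = 1L) {
  fixture(sprintf("cohort_s%g", strength), function() {
    cfg <- synth_config(n_subjects = 12, record_duration = 3600,
                        preictal_strength = strength, seed = gen_seed)
    cohort <- simulate_cohort(cfg)
    mont <- default_montage()
    feats <- list(); events <- list()
    for (id in names(cohort)) {
      s <- cohort[[id]]
      ev <- consensus_events(s$annotations, 2)
      merged <- merge_close_seizures(ev, 180)
      prec <- preprocess(derive_bipolar_montage(s$recording, mont))
      ep <- exclude_right_censored(label_epochs(prec, merged), merged, 600)
      feats[[id]] <- featurize(ep, prec, mont)
      events[[id]] <- ev
    }
    has <- vapply(cohort, `[[`, TRUE, "has_seizure")
    plan <- make_fold_plan(names(cohort), has, k = 10, seed = cv_seed)
    cv <- run_nested_cv(feats, plan, train_config(seed = cv_seed),
                        montage = mont)
    list(config = cfg, montage = mont, feats = feats, events = events,
         plan = plan, cv = cv)
  })
}

## Fraction of adjacent grid-cell pairs where `value` is non-decreasing
## along `along` within groups of `fixed`.
monotone_fraction <- function(df, value, along, fixed, decreasing = FALSE) {
  inc <- 0; tot <- 0
  for (g in unique(df[[fixed]])) {
    sub <- df[df[[fixed]] == g, ]
    v <- sub[[value]][order(sub[[along]])]
    d <- diff(v)
    d <- d[is.finite(d)]
    if (decreasing) d <- -d
    inc <- inc + sum(d >= -1e-12)
    tot <- tot + length(d)
  }
  inc / tot
}
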