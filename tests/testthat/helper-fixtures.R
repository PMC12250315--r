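# Shared fixtures built in code. The heavy end-to-end cohort runs are
# computed lazily and cached for the session so several tests can share
# one computation.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_cfg <- function(...) {
  synth_config(n_subjects = 2, record_duration = 1200, seed = 101, ...)
}

## A tiny featurized subject for sequence/forecaster plumbing tests.
tiny_featurized_subject <- function(strength = 0, seed = 101, subject = 1L) {
  cfg <- synth_config(n_subjects = 2, record_duration = 1200,
                      seizures_min = 1, seizures_max = 2,
                      preictal_strength = strength, seed = seed)
  bg <- generate_background(cfg, subject)
  inj <- inject_seizures(bg, cfg, subject)
  mont <- default_montage()
  prec <- preprocess(derive_bipolar_montage(inj$recording, mont))
  ev <- merge_close_seizures(inj$truth$seizure_events, 180)
  ep <- label_epochs(prec, ev)
  list(feats = featurize(ep, prec, mont), events = inj$truth$seizure_events,
       montage = mont, recording = prec, epochs = ep)
}

## Separable synthetic sequence dataset: class signal in feature 1 mean.
toy_sequence_dataset <- function(n_per_class = 60, T_ = 5, F_ = 6,
                                 delta = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(stats::rnorm(n * T_ * F_), c(n, T_, F_))
  y <- rep(c(0L, 1L), each = n_per_class)
  x[y == 1, , 1] <- x[y == 1, , 1] + delta
  structure(list(x = x, label = y, trainable = rep(TRUE, n),
                 subject_id = rep(sprintf("T%02d", 1:12), length.out = n),
                 end_time_s = seq_len(n) * 20,
                 seq_len = T_,
                 feature_names = paste0("f", seq_len(F_))),
            class = "sequence_dataset")
}

## Constant-probability prediction trace on a regular 20-s grid.
manual_trace <- function(probs, subject = "S01", epoch_len = 20,
                         start = 0, record_end = NULL) {
  t0 <- start + (seq_along(probs) - 1) * epoch_len
  structure(list(subject_id = subject, epoch_start_s = t0,
                 epoch_len_s = epoch_len, preictal_prob = probs,
                 label = rep("interictal", length(probs)),
                 censor_flag = rep(FALSE, length(probs)),
                 record_end_s = record_end %||%
                   (start + length(probs) * epoch_len),
                 burn_in = 0L),
            class = "prediction_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
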