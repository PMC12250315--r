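test_that("sequence building yields one window per non-burn-in epoch", {
  fx <- fixture("tiny0", function() tiny_featurized_subject())
  n_ep <- nrow(fx$feats)
  ds <- build_sequences(fx$feats, 15L)
  expect_equal(dim(ds$x)[1], n_ep - 14L)
  expect_equal(dim(ds$x)[2], 15L)
  expect_equal(ds$end_time_s[1], fx$feats$epoch_start_s[15])
  ## window content: slice k of the last window is epoch n_ep-15+k
  cols <- attr(fx$feats, "feature_names")
  expect_equal(ds$x[dim(ds$x)[1], 3, ],
               unname(as.numeric(fx$feats[n_ep - 12, cols])))
  ## trainable windows are exactly the preictal/interictal label epochs
  lab <- as.character(fx$feats$label[15:n_ep])
  expect_equal(ds$trainable, lab %in% c("preictal", "interictal"))
  f5 <- fx$feats[1:5, ]
  attr(f5, "feature_names") <- attr(fx$feats, "feature_names")
  expect_error(suppressMessages(build_sequences(f5, 15L)), "enough epochs")
})

test_that("standardization fit on training windows gives mean 0, sd 1", {
  ds <- toy_sequence_dataset(seed = 11)
  std <- seizecast:::fit_standardizer(ds)
  z <- seizecast:::apply_standardizer(ds, std)
  for (j in 1:2) {
    v <- as.numeric(z$x[, , j])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(v) - 1), 1e-9)
  }
  bad <- ds; bad$feature_names <- rev(bad$feature_names)
  expect_error(seizecast:::apply_standardizer(bad, std), "schema mismatch")
})

test_that("fold plans are stratified partitions with disjoint test splits", {
  subjects <- sprintf("S%02d", 1:40)
  has <- rep(c(TRUE, FALSE), 20)
  plan <- make_fold_plan(subjects, has, k = 10, seed = 4)
  tests <- lapply(plan, `[[`, "test")
  expect_equal(sort(unlist(tests)), sort(subjects))
  expect_true(all(lengths(tests) == 4))
  for (f in seq_along(plan)) {
    expect_length(intersect(plan[[f]]$train, plan[[f]]$test), 0)
    expect_length(intersect(plan[[f]]$val, plan[[f]]$test), 0)
    expect_length(intersect(plan[[f]]$train, plan[[f]]$val), 0)
    n_sz <- sum(tests[[f]] %in% subjects[has])
    expect_true(abs(n_sz - 2) <= 1)
  }
  expect_identical(plan, make_fold_plan(subjects, has, k = 10, seed = 4))
  expect_error(make_fold_plan(subjects[1:5], has[1:5], k = 10), "smaller k")
  expect_error(make_fold_plan(subjects, rep(TRUE, 40), k = 10), "stratify")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  B <- 4; T_ <- 5; F_ <- 3
  x <- array(stats::rnorm(B * T_ * F_), c(B, T_, F_))
  y <- c(1, 0, 1, 0); w <- c(1.3, 0.7, 1.3, 0.7)
  params <- seizecast:::convlstm_init(F_, c(3L, 3L), 4L, seed = 9)
  cache <- seizecast:::convlstm_forward(params, x, keep_cache = TRUE)
  grads <- seizecast:::convlstm_backward(params, cache, y, w)
  d <- attr(params, "dims")
  num_grad <- function(get, set) {
    eps <- 1e-5
    p0 <- as.array(get(params))
    g <- array(0, dim(p0))
    for (k in seq_along(p0)) {
      v <- p0; v[k] <- v[k] + eps
      lp <- seizecast:::convlstm_loss(
        seizecast:::convlstm_forward(set(params, v), x), y, w)
      v[k] <- v[k] - 2 * eps
      lm <- seizecast:::convlstm_loss(
        seizecast:::convlstm_forward(set(params, v), x), y, w)
      g[k] <- (lp - lm) / (2 * eps)
    }
    g
  }
  reset <- function(p) { attr(p, "dims") <- d; p }
  checks <- list(
    Wx = list(function(p) p$Wx,
              function(p, v) reset(modifyList(p, list(Wx = matrix(v, nrow(p$Wx)))))),
    Wh = list(function(p) p$Wh,
              function(p, v) reset(modifyList(p, list(Wh = matrix(v, nrow(p$Wh)))))),
    bl = list(function(p) p$bl,
              function(p, v) reset(modifyList(p, list(bl = as.numeric(v))))),
    wo = list(function(p) p$wo,
              function(p, v) reset(modifyList(p, list(wo = matrix(v, nrow(p$wo)))))),
    b2 = list(function(p) p$b2,
              function(p, v) reset(modifyList(p, list(b2 = as.numeric(v)))))
  )
  for (nm in names(checks)) {
    num <- num_grad(checks[[nm]][[1]], checks[[nm]][[2]])
    ana <- as.array(grads[[nm]])
    expect_lt(max(abs(ana - num)) / (max(abs(num)) + 1e-8), 1e-5)
  }
  ## convolution weights (list-of-matrices parameters)
  for (o in c(1L, 3L)) {
    num <- num_grad(function(p) p$W1[[o]], function(p, v) {
      p$W1[[o]] <- matrix(v, nrow(p$W1[[o]])); reset(p)
    })
    expect_lt(max(abs(grads$W1[[o]] - num)) / (max(abs(num)) + 1e-8), 1e-5)
  }
})

test_that("the ConvLSTM learns a separable toy task deterministically", {
  ds <- toy_sequence_dataset(n_per_class = 80, delta = 1.5, seed = 21)
  val <- toy_sequence_dataset(n_per_class = 40, delta = 1.5, seed = 22)
  cfg <- train_config(seq_len = 5L, conv_widths = c(4L, 8L), hidden = 8L,
                      max_epochs = 10L, batch_size = 32L, seed = 77)
  m <- train_forecaster(ds, val, cfg)
  expect_s3_class(m, "seizure_forecaster")
  p_val <- seizecast:::forecaster_probs(
    m, seizecast:::apply_standardizer(val, m$standardizer)$x)
  expect_gt(auroc(p_val, val$label), 0.85)
  expect_true(all(p_val >= 0 & p_val <= 1))
  ## seeded determinism of the whole loss trajectory
  m2 <- train_forecaster(ds, val, cfg)
  expect_identical(m$fit$history, m2$fit$history)
  ## single-class training set errors
  one <- ds; one$label <- rep(1L, length(one$label))
  expect_error(train_forecaster(one, val, cfg), "both preictal and interictal")
})

test_that("the logistic baseline satisfies the same contract", {
  ds <- toy_sequence_dataset(n_per_class = 80, delta = 1.5, seed = 31)
  val <- toy_sequence_dataset(n_per_class = 40, delta = 1.5, seed = 32)
  cfg <- train_config(arch = "logistic", seq_len = 5L)
  m <- train_forecaster(ds, NULL, cfg)
  p <- seizecast:::forecaster_probs(
    m, seizecast:::apply_standardizer(val, m$standardizer)$x)
  expect_gt(auroc(p, val$label), 0.9)
  expect_type(coef(m), "double")
  ## shuffling labels within the training set destroys the signal
  shuf <- ds
  set.seed(33); shuf$label <- sample(shuf$label)
  m0 <- train_forecaster(shuf, NULL, cfg)
  p0 <- seizecast:::forecaster_probs(
    m0, seizecast:::apply_standardizer(val, m0$standardizer)$x)
  expect_lt(abs(auroc(p0, val$label) - 0.5), 0.15)
})

test_that("plugin architectures run through the same interfaces", {
  ds <- toy_sequence_dataset(n_per_class = 40, seed = 41)
  mean_clf <- list(
    fit = function(x, y, w, cfg) {
      mu1 <- mean(x[y == 1, , 1]); mu0 <- mean(x[y == 0, , 1])
      list(mid = (mu1 + mu0) / 2, sign = sign(mu1 - mu0))
    },
    predict = function(model, x)
      1 / (1 + exp(-model$sign * (apply(x[, , 1, drop = FALSE], 1, mean) - model$mid))))
  cfg <- train_config(arch = mean_clf, seq_len = 5L)
  m <- train_forecaster(ds, NULL, cfg)
  expect_equal(m$arch, "plugin")
  p <- seizecast:::forecaster_probs(
    m, seizecast:::apply_standardizer(ds, m$standardizer)$x)
  expect_gt(auroc(p, ds$label), 0.9)
})

test_that("prediction traces are continuous, bounded and burn-in aware", {
  fx <- fixture("tiny2", function() tiny_featurized_subject(strength = 2,
                                                            subject = 2L))
  ds <- build_sequences(fx$feats, 5L)
  cfg <- train_config(seq_len = 5L, conv_widths = c(4L, 8L), hidden = 8L,
                      max_epochs = 3L, seed = 7)
  m <- train_forecaster(ds, NULL, cfg)
  tr <- predict_trace(m, fx$feats)
  expect_s3_class(tr, "prediction_trace")
  expect_length(tr$preictal_prob, nrow(fx$feats) - 4L)
  expect_true(all(tr$preictal_prob >= 0 & tr$preictal_prob <= 1))
  expect_equal(tr$burn_in, 4L)
  ## the trace covers excluded/ictal epochs too
  expect_true(all(c("ictal", "excluded") %in% tr$label) ||
                all(tr$label %in% c("ictal", "preictal", "interictal", "excluded")))
  ## schema mismatch is named
  broken <- fx$feats
  cols <- attr(broken, "feature_names")
  attr(broken, "feature_names") <- rev(cols)
  expect_error(predict_trace(m, broken), "mismatch")
})

test_that("nested CV isolates test subjects and audits leakage", {
  co_feats <- fixture("cv_small", function() {
    cfg <- synth_config(n_subjects = 6, record_duration = 1200,
                        seizures_min = 1, seizures_max = 2,
                        preictal_strength = 2, seed = 207)
    cohort <- simulate_cohort(cfg)
    mont <- default_montage()
    feats <- lapply(cohort, function(s) {
      ev <- merge_close_seizures(consensus_events(s$annotations, 2), 180)
      prec <- preprocess(derive_bipolar_montage(s$recording, mont))
      featurize(exclude_right_censored(label_epochs(prec, ev), ev, 600),
                prec, mont)
    })
    list(feats = feats, mont = mont,
         has = vapply(cohort, `[[`, TRUE, "has_seizure"))
  })
  plan <- make_fold_plan(names(co_feats$feats), co_feats$has, k = 3, seed = 2)
  cfg <- train_config(seq_len = 5L, conv_widths = c(4L, 8L), hidden = 8L,
                      max_epochs = 3L, seed = 13)
  cv <- run_nested_cv(co_feats$feats, plan, cfg, montage = co_feats$mont)
  expect_s3_class(cv, "nested_cv")
  expect_equal(nrow(cv$metrics), 3 + 2)
  expect_true(check_leakage(cv))
  expect_setequal(names(cv$traces), names(co_feats$feats))
  ## fold AUROC equals the rank oracle on that fold's (prob, label) pairs
  f1_subjects <- plan[[1]]$test
  probs <- labs <- c()
  for (id in f1_subjects) {
    tr <- cv$traces[[id]]
    ok <- tr$label %in% c("preictal", "interictal")
    probs <- c(probs, tr$preictal_prob[ok])
    labs <- c(labs, as.integer(tr$label[ok] == "preictal"))
  }
  expect_equal(cv$metrics$auroc[1], auroc(probs, labs))
  ## augmented copies inherit the parent assignment
  expect_equal(parent_subject("S03#lrfb"), "S03")
  aug <- augmented_copies(co_feats$feats[[1]], co_feats$mont)
  expect_length(aug, 4)
  expect_equal(unique(parent_subject(vapply(aug, function(a) a$subject_id[1], ""))),
               co_feats$feats[[1]]$subject_id[1])
})
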