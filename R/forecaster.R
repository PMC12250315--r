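#' Training configuration for the sequence forecaster
#'
#' @param arch architecture: `"convlstm"` (native reference
#'   implementation), `"logistic"` (ridge-penalized logistic regression
#'   on the flattened window, a classical ML baseline), or a plugin: a
#'   list with functions `fit(x, y, weights, cfg)` and
#'   `predict(model, x)` over n x T x F arrays, satisfying the same
#'   contract (covers the other benchmark architectures).
#' @param seq_len window length T in epochs (default 15 epochs = 5 min,
#'   matching the preictal span).
#' @param conv_widths channel widths of the two convolution blocks.
#' @param hidden LSTM hidden size.
#' @param dropout dropout rate on the final hidden state.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss, epochs.
#' @param class_weighting `"inverse_prevalence"` or `"none"`.
#' @param ridge_lambda penalty for the logistic baseline.
#' @param seed seed fixing initialization and shuffling.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(arch = "convlstm", seq_len = 15L,
                         conv_widths = c(16L, 32L), hidden = 32L,
                         dropout = 0.2, lr = 1e-3, batch_size = 128L,
                         max_epochs = 20L, patience = 4L,
                         class_weighting = c("inverse_prevalence", "none"),
                         ridge_lambda = 1e-2, seed = 1L) {
  structure(list(arch = arch, seq_len = as.integer(seq_len),
                 conv_widths = as.integer(conv_widths),
                 hidden = as.integer(hidden), dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 class_weighting = match.arg(class_weighting),
                 ridge_lambda = ridge_lambda, seed = as.integer(seed)),
            class = "train_config")
}

class_weights <- function(y, mode) {
  if (mode == "none") return(rep(1, length(y)))
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

#' Fit a preictal-state sequence forecaster
#'
#' Trains the configured architecture on the trainable (preictal vs
#' interictal) windows of the training set, with inverse-prevalence
#' class weights in a binary cross-entropy loss, early-stopping on the
#' validation loss. Per-feature standardization is fit on the training
#' windows only and stored with the model.
#'
#' @param train_ds,val_ds `"sequence_dataset"`s for the training and
#'   validation subjects (validation may be NULL: trains for
#'   `max_epochs` without early stopping).
#' @param cfg a [train_config()].
#' @return An object of class `"seizure_forecaster"`: the frozen
#'   parameters, the standardizer, the config, the training history and
#'   the subject ids seen during fitting (for leakage audits).
#' @export
train_forecaster <- function(train_ds, val_ds = NULL, cfg = train_config()) {
  tr_idx <- which(train_ds$trainable & !is.na(train_ds$label))
  y <- train_ds$label[tr_idx]
  if (length(unique(y)) < 2)
    stop("training set must contain both preictal and interictal windows")
  std <- fit_standardizer(ds_subset(train_ds, tr_idx))
  tr <- apply_standardizer(ds_subset(train_ds, tr_idx), std)
  w <- class_weights(y, cfg$class_weighting)
  va <- NULL; yv <- NULL; wv <- NULL
  if (!is.null(val_ds)) {
    va_idx <- which(val_ds$trainable & !is.na(val_ds$label))
    if (length(va_idx)) {
      va <- apply_standardizer(ds_subset(val_ds, va_idx), std)
      yv <- val_ds$label[va_idx]
      wv <- class_weights(yv, cfg$class_weighting)
    }
  }
  fit <- if (identical(cfg$arch, "convlstm")) {
    fit_convlstm(tr$x, y, w, va$x, yv, wv, cfg)
  } else if (identical(cfg$arch, "logistic")) {
    fit_logistic_flat(tr$x, y, w, cfg)
  } else if (is.list(cfg$arch) && is.function(cfg$arch$fit)) {
    list(model = cfg$arch$fit(tr$x, y, w, cfg), history = NULL,
         predict_fun = cfg$arch$predict)
  } else stop("unknown arch")
  structure(list(arch = if (is.list(cfg$arch)) "plugin" else cfg$arch,
                 fit = fit, standardizer = std, config = cfg,
                 feature_names = train_ds$feature_names,
                 seq_len = train_ds$seq_len,
                 trained_on = sort(unique(train_ds$subject_id[tr_idx])),
                 validated_on = if (is.null(val_ds)) character(0) else
                   sort(unique(val_ds$subject_id))),
            class = "seizure_forecaster")
}

fit_convlstm <- function(x, y, w, xv, yv, wv, cfg) {
  set.seed(cfg$seed)
  params <- convlstm_init(dim(x)[3], cfg$conv_widths, cfg$hidden, cfg$seed)
  state <- adam_init(params)
  n <- dim(x)[1]
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  stale <- 0L
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample(n)
    tl <- 0; nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
      cache <- convlstm_forward(params, x[idx, , , drop = FALSE],
                                dropout = cfg$dropout, keep_cache = TRUE)
      loss <- convlstm_loss(cache$p, y[idx], w[idx])
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             " (lr too high or degenerate features)")
      grads <- convlstm_backward(params, cache, y[idx], w[idx])
      upd <- adam_step(params, grads, state, lr = cfg$lr)
      params <- upd$params; state <- upd$state
      tl <- tl + loss; nb <- nb + 1L
    }
    vl <- NA_real_
    if (!is.null(xv)) {
      pv <- predict_in_batches(params, xv)
      vl <- convlstm_loss(pv, yv, wv)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = ep)
        stale <- 0L
      } else stale <- stale + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = tl / nb, val_loss = vl))
    if (!is.null(xv) && stale >= cfg$patience) break
  }
  final <- if (!is.null(xv) && is.finite(best$loss)) best$params else params
  list(params = final, history = history,
       best_epoch = if (!is.null(xv)) best$epoch else nrow(history))
}

predict_in_batches <- function(params, x, batch = 512L) {
  n <- dim(x)[1]
  p <- numeric(n)
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(n, b0 + batch - 1L)
    p[idx] <- convlstm_forward(params, x[idx, , , drop = FALSE])
  }
  p
}

## Ridge-penalized logistic regression on the flattened window,
## optimized by damped IRLS-free gradient descent via glm on a
## reduced problem is avoided: plain Newton steps on the penalized
## log-likelihood (dimensions are modest after flattening).
fit_logistic_flat <- function(x, y, w, cfg) {
  X <- cbind(1, matrix(x, dim(x)[1], dim(x)[2] * dim(x)[3]))
  beta <- numeric(ncol(X))
  lam <- cfg$ridge_lambda * dim(x)[1]
  pen <- c(0, rep(lam, ncol(X) - 1L))
  for (it in 1:25) {
    eta <- as.numeric(X %*% beta)
    p <- sigmoid(eta)
    g <- crossprod(X, w * (p - y)) + pen * beta
    Wd <- w * p * (1 - p)
    H <- crossprod(X, X * Wd) + diag(pen, ncol(X))
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    beta <- beta - step
    if (max(abs(step)) < 1e-8) break
  }
  list(beta = beta, history = NULL, best_epoch = NA_integer_)
}

#' @export
print.seizure_forecaster <- function(x, ...) {
  cat(sprintf("<seizure_forecaster> arch %s, T = %d epochs, %d features\n",
              x$arch, x$seq_len, length(x$feature_names)))
  cat("  trained on", length(x$trained_on), "subjects")
  if (!is.null(x$fit$best_epoch) && !is.na(x$fit$best_epoch))
    cat("; best epoch", x$fit$best_epoch)
  cat("\n")
  invisible(x)
}

#' @export
summary.seizure_forecaster <- function(object, ...) {
  print(object)
  if (!is.null(object$fit$history) && nrow(object$fit$history)) {
    cat("training history (loss):\n")
    print(utils::tail(object$fit$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.seizure_forecaster <- function(object, ...) {
  switch(object$arch,
         logistic = object$fit$beta,
         convlstm = object$fit$params,
         object$fit$model)
}

#' Emit a per-epoch preictal-probability trace for one subject
#'
#' Applies a fitted forecaster to every non-burn-in epoch of a
#' subject's featurized timeline, including epochs labeled excluded or
#' ictal, so the trace is continuous in time. The first `T - 1` epochs
#' form the burn-in period and carry no probability.
#'
#' @param model a `"seizure_forecaster"`.
#' @param feats featurized `"epoch_frame"` of a single subject, on the
#'   training feature schema.
#' @return A list of class `"prediction_trace"`: `subject_id`,
#'   `epoch_start_s`, `epoch_len_s`, `preictal_prob`, `label`,
#'   `censor_flag`, `record_end_s`, `burn_in` (count of dropped epochs).
#' @export
predict_trace <- function(model, feats) {
  stopifnot(inherits(model, "seizure_forecaster"))
  id <- unique(feats$subject_id)
  if (length(id) != 1) stop("predict_trace expects a single subject")
  ds <- build_sequences(feats, model$seq_len)
  ds <- apply_standardizer(ds, model$standardizer)
  p <- forecaster_probs(model, ds$x)
  structure(list(subject_id = id,
                 epoch_start_s = ds$end_time_s,
                 epoch_len_s = feats$epoch_len_s[1],
                 preictal_prob = p,
                 label = as.character(
                   feats$label[match(ds$end_time_s, feats$epoch_start_s)]),
                 censor_flag = feats$censor_flag[
                   match(ds$end_time_s, feats$epoch_start_s)],
                 record_end_s = attr(feats, "record_end_s"),
                 burn_in = model$seq_len - 1L),
            class = "prediction_trace")
}

forecaster_probs <- function(model, x) {
  p <- switch(model$arch,
    convlstm = predict_in_batches(model$fit$params, x),
    logistic = as.numeric(sigmoid(
      cbind(1, matrix(x, dim(x)[1], dim(x)[2] * dim(x)[3])) %*% model$fit$beta)),
    plugin = model$fit$predict_fun(model$fit$model, x))
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' @export
#' @rdname predict_trace
#' @param object,newdata standard predict-method aliases for
#'   `predict_trace(model, feats)`.
#' @param ... unused.
predict.seizure_forecaster <- function(object, newdata, ...) {
  if (length(unique(newdata$subject_id)) == 1L)
    return(predict_trace(object, newdata))
  lapply(split_epoch_frame(newdata), function(f) predict_trace(object, f))
}

split_epoch_frame <- function(feats) {
  out <- lapply(unique(feats$subject_id), function(id) {
    f <- feats[feats$subject_id == id, , drop = FALSE]
    attr(f, "record_end_s") <- attr(feats, "record_end_s")
    attr(f, "schema") <- attr(feats, "schema")
    attr(f, "feature_names") <- attr(feats, "feature_names")
    class(f) <- c("epoch_frame", "data.frame")
    f
  })
  names(out) <- unique(feats$subject_id)
  out
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("<prediction_trace> %s: %d epochs (burn-in %d), prob range [%.3f, %.3f]\n",
              x$subject_id, length(x$preictal_prob), x$burn_in,
              min(x$preictal_prob), max(x$preictal_prob)))
  invisible(x)
}

#' @export
plot.prediction_trace <- function(x, events = NULL, threshold = NULL, ...) {
  graphics::plot(x$epoch_start_s / 60, x$preictal_prob, type = "l",
                 xlab = "time (min)", ylab = "preictal probability",
                 ylim = c(0, 1), main = x$subject_id, ...)
  if (!is.null(events) && nrow(events))
    graphics::rect(events$onset_s / 60, 0, events$offset_s / 60, 1,
                   col = grDevices::adjustcolor("red", 0.2), border = NA)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2)
  invisible(x)
}
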