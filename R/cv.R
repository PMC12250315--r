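#' Augmented copies of a subject's featurized epochs
#'
#' Returns the original frame plus the three transposition augmentations
#' (left-right, front-back, both), each under a derived subject id
#' `"<parent>#lr"` etc. so sequence windows never mix copies while the
#' parent assignment remains recoverable (see [parent_subject()]).
#'
#' @param feats single-subject featurized `"epoch_frame"`.
#' @param montage the [montage_spec()].
#' @return List of four epoch frames.
#' @export
augmented_copies <- function(feats, montage) {
  out <- list(feats)
  for (w in c("lr", "fb", "lrfb")) {
    a <- augment_features(feats, montage, w)
    a$subject_id <- paste0(feats$subject_id[1], "#", w)
    out[[length(out) + 1L]] <- a
  }
  out
}

#' Parent subject id of an (possibly augmented) subject id
#' @param id subject id, possibly suffixed `#lr`, `#fb` or `#lrfb`.
#' @return The parent id.
#' @export
parent_subject <- function(id) sub("#.*$", "", id)

rbind_epoch_frames <- function(frames) {
  out <- do.call(rbind, frames)
  attr(out, "record_end_s") <- attr(frames[[1]], "record_end_s")
  attr(out, "schema") <- attr(frames[[1]], "schema")
  attr(out, "feature_names") <- attr(frames[[1]], "feature_names")
  class(out) <- c("epoch_frame", "data.frame")
  out
}

#' Nested subject-stratified cross-validation of the forecaster
#'
#' For every fold of the plan: trains on the training subjects (with
#' transposition augmentation of training data only), early-stops on
#' the validation subjects, and emits prediction traces for the test
#' subjects. Reports per-fold epoch-level AUROC / AUPRC / F1 of
#' preictal-vs-interictal classification plus their mean and standard
#' error across folds. Each subject is tested exactly once, so the
#' union of test traces covers the cohort.
#'
#' @param features_by_subject named list of single-subject featurized
#'   `"epoch_frame"`s.
#' @param plan a [make_fold_plan()].
#' @param cfg a [train_config()].
#' @param montage [montage_spec()] used for augmentation.
#' @param augment augment training folds with channel transpositions?
#' @return A list of class `"nested_cv"`: `traces` (one per subject),
#'   `metrics` (per-fold rows plus mean/se), `models`, and `audit`
#'   (per-fold subject assignments actually used, for leakage checks).
#' @export
run_nested_cv <- function(features_by_subject, plan, cfg = train_config(),
                          montage = NULL, augment = TRUE) {
  if (augment && is.null(montage))
    stop("augmentation requires the montage spec")
  traces <- list(); models <- list(); audit <- list()
  rows <- list()
  for (f in seq_along(plan)) {
    fold <- plan[[f]]
    tr_frames <- list()
    for (id in fold$train) {
      if (augment) tr_frames <- c(tr_frames,
                                  augmented_copies(features_by_subject[[id]], montage))
      else tr_frames <- c(tr_frames, list(features_by_subject[[id]]))
    }
    tr_ds <- build_sequences(rbind_epoch_frames(tr_frames), cfg$seq_len)
    va_ds <- if (length(fold$val))
      build_sequences(rbind_epoch_frames(features_by_subject[fold$val]),
                      cfg$seq_len)
    else NULL
    model <- tryCatch(
      train_forecaster(tr_ds, va_ds, cfg),
      error = function(e) e)
    if (inherits(model, "error")) {
      rows[[f]] <- data.frame(fold = f, auroc = NA, auprc = NA, f1 = NA,
                              n_test_epochs = 0, failed = TRUE,
                              message = conditionMessage(model))
      next
    }
    models[[f]] <- model
    audit[[f]] <- list(
      train = sort(unique(parent_subject(model$trained_on))),
      val = sort(unique(parent_subject(model$validated_on))),
      test = sort(fold$test),
      standardized_on = sort(unique(parent_subject(model$trained_on))))
    probs <- numeric(0); labs <- integer(0)
    for (id in fold$test) {
      tr <- predict_trace(model, features_by_subject[[id]])
      traces[[id]] <- tr
      ok <- tr$label %in% c("preictal", "interictal")
      probs <- c(probs, tr$preictal_prob[ok])
      labs <- c(labs, as.integer(tr$label[ok] == "preictal"))
    }
    rows[[f]] <- data.frame(fold = f,
                            auroc = auroc(probs, labs),
                            auprc = auprc(probs, labs),
                            f1 = f1_score(probs, labs),
                            n_test_epochs = length(labs),
                            failed = FALSE, message = "")
  }
  metrics <- do.call(rbind, rows)
  msum <- data.frame(
    fold = c(NA, NA),
    auroc = c(mean(metrics$auroc, na.rm = TRUE),
              stats::sd(metrics$auroc, na.rm = TRUE) /
                sqrt(sum(is.finite(metrics$auroc)))),
    auprc = c(mean(metrics$auprc, na.rm = TRUE),
              stats::sd(metrics$auprc, na.rm = TRUE) /
                sqrt(sum(is.finite(metrics$auprc)))),
    f1 = c(mean(metrics$f1, na.rm = TRUE),
           stats::sd(metrics$f1, na.rm = TRUE) /
             sqrt(sum(is.finite(metrics$f1)))),
    n_test_epochs = c(sum(metrics$n_test_epochs), NA),
    failed = c(any(metrics$failed), NA), message = c("mean", "se"))
  structure(list(traces = traces,
                 metrics = rbind(metrics, msum),
                 models = models, audit = audit, plan = plan, config = cfg),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  k <- length(x$plan)
  m <- x$metrics[seq_len(k), ]
  cat(sprintf("<nested_cv> %d folds; pooled test epochs %d\n",
              k, sum(m$n_test_epochs)))
  cat(sprintf("  epoch AUROC %.3f (se %.3f), AUPRC %.3f, F1 %.3f\n",
              x$metrics$auroc[k + 1], x$metrics$auroc[k + 2],
              x$metrics$auprc[k + 1], x$metrics$f1[k + 1]))
  invisible(x)
}

#' Pooled held-out probabilities and labels from a nested CV run
#'
#' Concatenates all test-subject trace epochs with preictal/interictal
#' labels (micro-averaging across subjects).
#'
#' @param cv a `"nested_cv"`.
#' @return data.frame with subject, epoch_start_s, prob, label.
#' @export
pooled_test_predictions <- function(cv) {
  rows <- lapply(cv$traces, function(tr) {
    ok <- tr$label %in% c("preictal", "interictal")
    data.frame(subject = tr$subject_id,
               epoch_start_s = tr$epoch_start_s[ok],
               prob = tr$preictal_prob[ok],
               label = as.integer(tr$label[ok] == "preictal"))
  })
  do.call(rbind, rows)
}

#' Verify that no test subject leaked into training
#'
#' Checks, for every fold, that the subjects actually used for
#' training, validation and standardization are disjoint from the test
#' subjects, that augmented copies followed their parent, and that each
#' subject is tested exactly once across folds.
#'
#' @param cv a `"nested_cv"`.
#' @return TRUE invisibly; stops with a description on violation.
#' @export
check_leakage <- function(cv) {
  tested <- character(0)
  for (f in seq_along(cv$audit)) {
    a <- cv$audit[[f]]
    if (is.null(a)) next
    for (part in c("train", "val", "standardized_on")) {
      bad <- intersect(a[[part]], a$test)
      if (length(bad))
        stop("fold ", f, ": test subject(s) ", paste(bad, collapse = ","),
             " appear in ", part)
    }
    if (length(intersect(a$train, a$val)))
      stop("fold ", f, ": train/validation overlap")
    tested <- c(tested, a$test)
  }
  if (anyDuplicated(tested))
    stop("subject(s) tested in more than one fold: ",
         paste(unique(tested[duplicated(tested)]), collapse = ","))
  invisible(TRUE)
}
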