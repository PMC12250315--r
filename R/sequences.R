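#' Build rolling-window sequence datasets from featurized epochs
#'
#' For every non-burn-in epoch of each subject, stacks the `T` most
#' recent consecutive epoch feature vectors into one window ending at
#' (and labeled by) that epoch. Windows never cross subjects, and the
#' epoch grid within a subject is contiguous by construction. Windows
#' whose label epoch is preictal or interictal are flagged trainable;
#' all others (ictal, excluded) remain in the dataset so continuous
#' prediction traces can be emitted.
#'
#' @param feats featurized `"epoch_frame"` (possibly several subjects
#'   row-bound; rows must be time-ordered within subject).
#' @param seq_len window length `T` in epochs.
#' @return A list of class `"sequence_dataset"`: `x` (n x T x F array),
#'   `label` (1 = preictal, 0 = interictal, NA otherwise), `trainable`,
#'   `subject_id`, `end_time_s` (label-epoch start time), `feature_names`.
#' @export
build_sequences <- function(feats, seq_len = 15L) {
  cols <- attr(feats, "feature_names")
  if (is.null(cols)) stop("epoch frame has no features; run featurize() first")
  xs <- list(); lab <- list(); subj <- list(); tt <- list(); trn <- list()
  for (id in unique(feats$subject_id)) {
    sub <- feats[feats$subject_id == id, , drop = FALSE]
    n <- nrow(sub)
    if (n < seq_len) {
      message("subject ", id, " has ", n, " epochs < T = ", seq_len,
              "; contributes no windows")
      next
    }
    fmat <- as.matrix(sub[, cols, drop = FALSE])
    ends <- seq_len:n
    arr <- array(NA_real_, c(length(ends), seq_len, ncol(fmat)))
    for (k in seq_len(seq_len))
      arr[, k, ] <- fmat[ends - seq_len + k, , drop = FALSE]
    xs[[id]] <- arr
    l <- as.character(sub$label[ends])
    lab[[id]] <- ifelse(l == "preictal", 1L, ifelse(l == "interictal", 0L, NA))
    trn[[id]] <- l %in% c("preictal", "interictal")
    subj[[id]] <- rep(id, length(ends))
    tt[[id]] <- sub$epoch_start_s[ends]
  }
  if (!length(xs)) stop("no subject has enough epochs for T = ", seq_len)
  n_tot <- sum(vapply(xs, function(a) dim(a)[1], 0L))
  x <- array(NA_real_, c(n_tot, seq_len, length(cols)))
  at <- 0L
  for (a in xs) { x[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
  structure(list(x = x,
                 label = unlist(lab, use.names = FALSE),
                 trainable = unlist(trn, use.names = FALSE),
                 subject_id = unlist(subj, use.names = FALSE),
                 end_time_s = unlist(tt, use.names = FALSE),
                 seq_len = as.integer(seq_len),
                 feature_names = cols),
            class = "sequence_dataset")
}

#' Subject-stratified nested cross-validation fold plan
#'
#' Partitions subjects into `k` disjoint test splits, stratified on the
#' has-seizure flag; within each fold the remaining subjects are split
#' into training and validation (also stratified), targeting the given
#' fractions of all subjects. Augmented copies of a subject always
#' follow the parent's assignment.
#'
#' @param subjects character vector of subject ids.
#' @param has_seizure logical vector aligned with `subjects`.
#' @param k number of folds.
#' @param fractions `c(train, validation, test)` fractions summing to 1.
#' @param seed RNG seed; fixes the plan.
#' @return A list of class `"fold_plan"`: per fold, `train`, `val`,
#'   `test` subject-id vectors.
#' @export
make_fold_plan <- function(subjects, has_seizure, k = 10L,
                           fractions = c(0.675, 0.225, 0.10), seed = 1L) {
  stopifnot(length(subjects) == length(has_seizure),
            abs(sum(fractions) - 1) < 1e-9)
  if (length(subjects) < k)
    stop("need at least k = ", k, " subjects; have ", length(subjects),
         " (use a smaller k)")
  if (sum(has_seizure) < 1 || sum(!has_seizure) < 1)
    stop("need subjects both with and without seizures to stratify")
  set.seed(seed)
  ## deal each stratum round-robin into k test folds
  fold_of <- integer(length(subjects))
  for (stratum in c(TRUE, FALSE)) {
    idx <- sample(which(has_seizure == stratum))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  val_share <- fractions[2] / (fractions[1] + fractions[2])
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test <- subjects[fold_of == f]
    rest <- which(fold_of != f)
    val_pick <- logical(length(subjects))
    for (stratum in c(TRUE, FALSE)) {
      pool <- sample(intersect(rest, which(has_seizure == stratum)))
      n_val <- round(length(pool) * val_share)
      ## keep at least one subject of each stratum in training
      n_val <- min(n_val, length(pool) - 1L)
      if (n_val > 0) val_pick[pool[seq_len(n_val)]] <- TRUE
    }
    folds[[f]] <- list(train = subjects[fold_of != f & !val_pick],
                       val = subjects[fold_of != f & val_pick],
                       test = test)
  }
  structure(folds, class = "fold_plan",
            subjects = subjects, has_seizure = has_seizure, k = k)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d subjects\n",
              attr(x, "k"), length(attr(x, "subjects"))))
  for (f in seq_along(x))
    cat(sprintf("  fold %2d: train %d / val %d / test %d (%s)\n", f,
                length(x[[f]]$train), length(x[[f]]$val), length(x[[f]]$test),
                paste(x[[f]]$test, collapse = ",")))
  invisible(x)
}

## Subset a sequence_dataset by row index.
ds_subset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , , drop = FALSE],
                 label = ds$label[idx],
                 trainable = ds$trainable[idx],
                 subject_id = ds$subject_id[idx],
                 end_time_s = ds$end_time_s[idx],
                 seq_len = ds$seq_len,
                 feature_names = ds$feature_names),
            class = "sequence_dataset")
}

## Fit per-feature standardization on a dataset (over windows x time).
fit_standardizer <- function(ds) {
  f <- dim(ds$x)[3]
  mu <- numeric(f); sdv <- numeric(f)
  for (j in seq_len(f)) {
    v <- ds$x[, , j]
    mu[j] <- mean(v)
    sdv[j] <- stats::sd(as.numeric(v))
    if (!is.finite(sdv[j]) || sdv[j] == 0) sdv[j] <- 1
  }
  list(mu = mu, sd = sdv, feature_names = ds$feature_names)
}

apply_standardizer <- function(ds, std) {
  if (!identical(std$feature_names, ds$feature_names))
    stop("feature schema mismatch; first differing column: ",
         ds$feature_names[which(ds$feature_names != std$feature_names)[1]])
  for (j in seq_len(dim(ds$x)[3]))
    ds$x[, , j] <- (ds$x[, , j] - std$mu[j]) / std$sd[j]
  ds
}
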