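# The single-session classification pipeline: band-pass filter, channel
# subset, per-split CSP + Fisher discriminant, mean cross-validated accuracy;
# plus the two baselines and cross-session transfer.

#' Cross-validation configuration
#'
#' Stratified k-fold splits generated once from a fixed seed, so every subset
#' and variant evaluated on a session shares identical folds.
#'
#' @param n_splits Number of folds, `>= 2` (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param stratified Kept for interface completeness; splits are always
#'   stratified.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_splits = 5, seed = 42L, stratified = TRUE) {
  if (!is_count(n_splits, 2L)) validation_error("'n_splits' must be >= 2")
  if (!isTRUE(stratified)) validation_error("only stratified splitting is supported")
  structure(list(n_splits = as.integer(n_splits), seed = as.integer(seed),
                 stratified = TRUE),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' @param labels Per-trial class labels.
#' @param cv A [cv_config].
#' @return Integer vector of fold ids in `1..n_splits`, one per trial; every
#'   fold's class imbalance differs from the session's by at most one trial.
#' @export
make_folds <- function(labels, cv = cv_config()) {
  stopifnot(inherits(cv, "cv_config"))
  folds <- integer(length(labels))
  with_seed(cv$seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(cv$n_splits), length(idx))[sample.int(length(idx))]
    }
  })
  counts <- table(factor(folds, levels = seq_len(cv$n_splits)), labels)
  train_counts <- matrix(colSums(counts), nrow(counts), ncol(counts),
                         byrow = TRUE) - counts
  if (any(train_counts < 2L)) {
    validation_error("a training fold has fewer than 2 trials of some class")
  }
  folds
}

accuracy_result <- function(subset, fold_accuracies, per_trial_correct) {
  structure(list(subset = subset,
                 fold_accuracies = fold_accuracies,
                 mean_accuracy = mean(fold_accuracies),
                 correct = sum(per_trial_correct),
                 total = length(per_trial_correct),
                 per_trial_correct = per_trial_correct),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> mean accuracy %.3f (%d/%d trials, %d folds)\n",
              x$mean_accuracy, x$correct, x$total, length(x$fold_accuracies)))
  cat("  channels:", paste(x$subset, collapse = " "), "\n")
  invisible(x)
}

# Core CV loop on precomputed trial covariances. `idx` selects channels,
# `n_components` the retained CSP components. CSP and LDA are fit on training
# folds only.
crossval_from_covs <- function(covs, labels, folds, idx, n_components,
                               shrinkage = 0, subset_names = NULL) {
  n_splits <- max(folds)
  correct <- logical(length(labels))
  fold_acc <- numeric(n_splits)
  for (f in seq_len(n_splits)) {
    train <- which(folds != f)
    test <- which(folds == f)
    ccovs <- class_covs_from_trials(covs, labels, train, idx, shrinkage,
                                    ch_names = subset_names)
    model <- fit_csp(ccovs, n_components)
    ftrain <- csp_features_from_covs(model, covs, train, idx)
    ftest <- csp_features_from_covs(model, covs, test, idx)
    fit <- lda_fit(ftrain, labels[train])
    pred <- lda_predict(fit, ftest)
    correct[test] <- pred == labels[test]
    fold_acc[f] <- mean(correct[test])
  }
  accuracy_result(subset_names, fold_acc, correct)
}

#' Cross-validated pipeline accuracy on a channel subset
#'
#' Runs the full pipeline on one session: band-pass filter, restriction to the
#' subset, stratified k-fold cross-validation where each split fits CSP and the
#' Fisher discriminant on its training trials only and scores the held-out
#' trials. Deterministic given the session, subset and `cv$seed`.
#'
#' @param epochs An [eeg_epochs] session.
#' @param subset Channel subset (`NULL` = all channels).
#' @param cv A [cv_config].
#' @param filter A [filter_spec], or `NULL` to skip filtering (for data that
#'   are already band-limited).
#' @param n_components Retained CSP components; must not exceed the subset
#'   size.
#' @param shrinkage Covariance shrinkage fraction passed to the CSP step.
#' @return An object of class `accuracy_result` with per-fold accuracies,
#'   their mean, pooled correct/total counts and per-trial correctness flags.
#' @export
crossval_accuracy <- function(epochs, subset = NULL, cv = cv_config(),
                              filter = filter_spec(), n_components = 8,
                              shrinkage = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  sub_names <- if (is.null(subset)) epochs$ch_names else channel_subset(subset)
  idx_check <- match_channels(sub_names, epochs$ch_names)
  if (length(sub_names) < 2L) validation_error("subset must have >= 2 channels")
  if (n_components > length(sub_names)) {
    validation_error(sprintf("n_components (%d) exceeds subset size (%d)",
                             n_components, length(sub_names)))
  }
  filtered <- if (is.null(filter)) epochs else bandpass(epochs, filter)
  sub <- subset_channels(filtered, sub_names)
  covs <- trial_cov_array(sub)
  folds <- make_folds(sub$labels, cv)
  crossval_from_covs(covs, sub$labels, folds, seq_along(sub$ch_names),
                     n_components, shrinkage, subset_names = sub$ch_names)
}

#' Full-electrode baseline (BFull)
#'
#' The pipeline run on every channel of the session.
#'
#' @inheritParams crossval_accuracy
#' @return An `accuracy_result`.
#' @export
baseline_bfull <- function(epochs, cv = cv_config(), filter = filter_spec(),
                           n_components = 8, shrinkage = 0) {
  crossval_accuracy(epochs, subset = NULL, cv = cv, filter = filter,
                    n_components = n_components, shrinkage = shrinkage)
}

#' Fixed-montage baseline (B16)
#'
#' The pipeline restricted to a fixed reduced montage, by default the
#' 16-electrode sensorimotor set of [montage_16()].
#'
#' @inheritParams crossval_accuracy
#' @param montage Channel names of the reduced montage.
#' @return An `accuracy_result`.
#' @export
baseline_b16 <- function(epochs, montage = montage_16(), cv = cv_config(),
                         filter = filter_spec(), n_components = 8,
                         shrinkage = 0) {
  crossval_accuracy(epochs, subset = montage, cv = cv, filter = filter,
                    n_components = n_components, shrinkage = shrinkage)
}

#' Cross-session transfer accuracy
#'
#' Fits CSP and the discriminant on the whole training session and scores the
#' whole test session as a single fold — the check of whether an electrode
#' combination found in one session still performs in another.
#'
#' @param train,test [eeg_epochs] sessions containing the subset channels.
#' @param subset Channel subset (`NULL` = all channels of `train`).
#' @param filter A [filter_spec] or `NULL`.
#' @param n_components Retained CSP components.
#' @param shrinkage Covariance shrinkage fraction.
#' @return An `accuracy_result` with a single fold.
#' @export
transfer_accuracy <- function(train, test, subset = NULL,
                              filter = filter_spec(), n_components = 8,
                              shrinkage = 0) {
  stopifnot(inherits(train, "eeg_epochs"), inherits(test, "eeg_epochs"))
  sub_names <- if (is.null(subset)) train$ch_names else channel_subset(subset)
  tr <- subset_channels(if (is.null(filter)) train else bandpass(train, filter),
                        sub_names)
  te <- subset_channels(if (is.null(filter)) test else bandpass(test, filter),
                        sub_names)
  if (n_components > length(sub_names)) {
    validation_error(sprintf("n_components (%d) exceeds subset size (%d)",
                             n_components, length(sub_names)))
  }
  ccovs <- class_covariances(tr, shrinkage)
  model <- fit_csp(ccovs, n_components)
  fit <- lda_fit(apply_csp(model, tr), tr$labels)
  pred <- lda_predict(fit, apply_csp(model, te))
  correct <- pred == te$labels
  accuracy_result(sub_names, mean(correct), correct)
}

#' Percentage change of an accuracy against a baseline
#'
#' `100 * (acc - base) / base`, the per-subject effect measure used by the
#' subset search.
#'
#' @param acc,base Accuracies as fractions; `base > 0`.
#' @return Percentage change.
#' @export
percentage_change <- function(acc, base) {
  if (any(base <= 0)) domain_error("baseline accuracy must be > 0")
  100 * (acc - base) / base
}
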