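# Shared fixtures, built in code.

# Small white-noise session: 2 classes, `n_ch` channels, no class contrast.
noise_session <- function(n_trials = 8, n_ch = 3, n_samples = 64, seed = 1,
                          sfreq = 128, ch_names = NULL) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n_trials * n_ch * n_samples),
                   c(n_trials, n_ch, n_samples)),
             labels = rep(c("left", "right"), length.out = n_trials),
             ch_names = ch_names %||% montage_16()[seq_len(n_ch)],
             sfreq = sfreq)
}

# Fast synthetic session with a planted contrast.
quick_session <- function(seed = 1, n_ch = 6, n_trials = 30, effect = 8,
                          disc = c("C3", "C4"), mixing = 0, n_samples = 128) {
  generate_session(sim_config(n_channels = n_ch, n_trials_per_class = n_trials,
                              n_samples = n_samples, disc_channels = disc,
                              effect = effect, mixing_strength = mixing,
                              seed = seed))
}

# Minimal accuracy_result stand-in for the Bayesian evaluator.
fake_result <- function(correct, total, subset = c("C3", "C4"), acc = NULL) {
  flags <- rep(c(TRUE, FALSE), c(correct, total - correct))
  structure(list(subset = subset, fold_accuracies = correct / total,
                 mean_accuracy = acc %||% (correct / total),
                 correct = correct, total = total, per_trial_correct = flags),
            class = "accuracy_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A random symmetric positive-definite matrix.
random_spd <- function(n, jitter = 0.1) {
  a <- matrix(rnorm(n * n), n)
  tcrossprod(a) + jitter * diag(n)
}
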