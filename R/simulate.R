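# Synthetic two-class EEG sessions with a known band-power contrast.
#
# Each channel carries a band-limited Gaussian oscillation (unit variance)
# plus broadband Gaussian noise. The class contrast is a multiplicative
# variance boost of the oscillation on the discriminative channels: "left"
# trials boost the first half of `disc_channels`, "right" trials the second
# half, so both tails of a CSP decomposition see discriminative components.
# An optional fixed tridiagonal mixing operator leaks signal between
# neighbouring channels, emulating volume conduction.

# Montage defaults by descending sensorimotor relevance, reported in
# montage order.
default_montage <- function(n_channels) {
  m16 <- montage_16()
  if (n_channels <= 16L) {
    pref <- c("C3", "C4", "Cz", "FC3", "FC4", "CP3", "CP4", "FCz",
              "CPz", "C1", "C2", "FC1", "FC2", "CP1", "CP2", "Fz")
    keep <- pref[seq_len(n_channels)]
    m16[m16 %in% keep]
  } else {
    c(m16, sprintf("CH%02d", seq_len(n_channels - 16L)))
  }
}

#' Configuration of a synthetic EEG session
#'
#' @param n_channels Number of channels.
#' @param ch_names Channel names; defaults to [montage_16()] when
#'   `n_channels = 16`, otherwise to the `n_channels` most central
#'   sensorimotor 10-10 positions.
#' @param n_trials_per_class Trials per class (labels are balanced).
#' @param n_samples Samples per trial.
#' @param sfreq Sampling rate in Hz (`>= 90`).
#' @param disc_channels Channels carrying the class contrast (subset of
#'   `ch_names`; may be empty for a pure null session).
#' @param effect Variance ratio `>= 1` applied to the oscillation on the
#'   boosted channels. `effect = 1` makes the two classes exchangeable.
#' @param band Passband of the oscillatory component in Hz.
#' @param noise_sd Broadband noise standard deviation (oscillation sd is 1).
#' @param mixing_strength Off-diagonal neighbour-leakage coefficient in
#'   `[0, 1)`; 0 disables spatial mixing.
#' @param seed Integer seed; all output is a pure function of the config.
#' @param subject_id Identifier stamped on generated sessions.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 16, ch_names = NULL,
                       n_trials_per_class = 50, n_samples = 256, sfreq = 128,
                       disc_channels = c("C3", "C4"), effect = 4,
                       band = c(8, 30), noise_sd = 0.3,
                       mixing_strength = 0.2, seed = 1L,
                       subject_id = "subject-1") {
  if (!is_count(n_channels, 2L)) validation_error("'n_channels' must be >= 2")
  ch_names <- canonical_channels(ch_names %||% default_montage(n_channels))
  if (length(ch_names) != n_channels || anyDuplicated(ch_names)) {
    validation_error("'ch_names' must be n_channels unique names")
  }
  disc_channels <- canonical_channels(as.character(disc_channels))
  if (!all(toupper(disc_channels) %in% toupper(ch_names))) {
    validation_error("'disc_channels' must be a subset of 'ch_names'")
  }
  if (!is_count(n_trials_per_class, 1L)) {
    validation_error("'n_trials_per_class' must be >= 1")
  }
  if (!is_count(n_samples, 8L)) validation_error("'n_samples' must be >= 8")
  if (!is.numeric(sfreq) || sfreq < 90) validation_error("'sfreq' must be >= 90 Hz")
  if (!is.numeric(effect) || length(effect) != 1L || effect < 1) {
    validation_error("'effect' must be a variance ratio >= 1")
  }
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= sfreq / 2) {
    validation_error("'band' must satisfy 0 < low < high < sfreq/2")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) validation_error("'noise_sd' must be >= 0")
  if (!is.numeric(mixing_strength) || mixing_strength < 0 || mixing_strength >= 1) {
    validation_error("'mixing_strength' must be in [0, 1)")
  }
  structure(list(n_channels = as.integer(n_channels), ch_names = ch_names,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 n_samples = as.integer(n_samples), sfreq = sfreq,
                 disc_channels = disc_channels, effect = effect, band = band,
                 noise_sd = noise_sd, mixing_strength = mixing_strength,
                 seed = as.integer(seed), subject_id = subject_id),
            class = "sim_config")
}

# Row-normalized identity-plus-neighbour-leakage mixing operator. Fixed
# function of channel order, independent of the seed.
mixing_matrix <- function(n_channels, strength) {
  M <- diag(n_channels)
  for (i in seq_len(n_channels)) {
    if (i > 1L) M[i, i - 1L] <- strength
    if (i < n_channels) M[i, i + 1L] <- strength
  }
  M / rowSums(M)
}

#' Generate one synthetic two-class session
#'
#' @param config A [sim_config].
#' @param session_id Identifier for the generated session.
#' @return An [eeg_epochs] object with `2 * n_trials_per_class` balanced
#'   trials.
#' @export
#' @examples
#' ep <- generate_session(sim_config(n_channels = 4, n_trials_per_class = 10,
#'                                   disc_channels = c("C3", "C4"), seed = 7))
#' ep
generate_session <- function(config, session_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  session_id <- session_id %||% sprintf("sim-%d", config$seed)
  with_seed(config$seed, {
    n_trials <- 2L * config$n_trials_per_class
    n_ch <- config$n_channels
    n_s <- config$n_samples
    labels <- rep(c("left", "right"), each = config$n_trials_per_class)
    flt <- signal::butter(4, config$band / (config$sfreq / 2), type = "pass")

    # Band-limited unit-variance oscillation: one long filtered noise stream
    # per channel, cut into trials.
    x <- array(0, c(n_trials, n_ch, n_s))
    for (ch in seq_len(n_ch)) {
      stream <- filtfilt_refl(flt, stats::rnorm(n_trials * n_s))
      stream <- stream / stats::sd(stream)
      x[, ch, ] <- matrix(stream, n_trials, n_s, byrow = TRUE)
    }

    # Variance boost on the discriminative channels, split between classes.
    if (length(config$disc_channels)) {
      disc_idx <- match_channels(config$disc_channels, config$ch_names)
      n_d <- length(disc_idx)
      left_idx <- disc_idx[seq_len(ceiling(n_d / 2))]
      right_idx <- setdiff(disc_idx, left_idx)
      gain <- sqrt(config$effect)
      x[labels == "left", left_idx, ] <- x[labels == "left", left_idx, ] * gain
      if (length(right_idx)) {
        x[labels == "right", right_idx, ] <- x[labels == "right", right_idx, ] * gain
      }
    }

    if (config$noise_sd > 0) {
      x <- x + array(stats::rnorm(length(x), sd = config$noise_sd), dim(x))
    }

    if (config$mixing_strength > 0) {
      M <- mixing_matrix(n_ch, config$mixing_strength)
      for (tr in seq_len(n_trials)) x[tr, , ] <- M %*% x[tr, , ]
    }

    eeg_epochs(x, labels, config$ch_names, config$sfreq,
               session_id = session_id, subject_id = config$subject_id)
  })
}

#' Generate several sessions of one synthetic subject
#'
#' Sessions share the discriminative channels and effect size but use distinct
#' seeds derived deterministically from `config$seed`, so repeated calls give
#' identical session lists.
#'
#' @param config A [sim_config].
#' @param n_sessions Number of sessions, `>= 1`.
#' @return List of [eeg_epochs], one per session, with distinct `session_id`s.
#' @export
generate_subject <- function(config, n_sessions) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n_sessions, 1L)) validation_error("'n_sessions' must be >= 1")
  lapply(seq_len(n_sessions), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    generate_session(cfg, session_id = sprintf("%s-session-%d",
                                               config$subject_id, i))
  })
}
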