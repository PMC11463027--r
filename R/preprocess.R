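# Band-pass filtering of epoched data.

#' Band-pass filter specification
#'
#' Defaults to the 5-45 Hz band used throughout the classification pipeline,
#' realized as a Butterworth design applied forward-backward (zero phase) with
#' odd reflective padding at the epoch edges.
#'
#' @param low,high Band edges in Hz; `0 < low < high`, and `high` must be below
#'   the Nyquist frequency when applied.
#' @param order Butterworth design order (default 4).
#' @param zero_phase Apply the filter forward and backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 5, high = 45, order = 4, zero_phase = TRUE) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low) {
    validation_error("need 0 < low < high")
  }
  if (!is_count(order, 1L)) validation_error("'order' must be a positive integer")
  structure(list(low = low, high = high, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Design a Butterworth band-pass for a given sampling rate.
design_bandpass <- function(spec, sfreq) {
  nyq <- sfreq / 2
  if (spec$high >= nyq) {
    validation_error(sprintf(
      "high edge %g Hz is not below Nyquist (%g Hz at sfreq = %g Hz)",
      spec$high, nyq, sfreq))
  }
  signal::butter(spec$order, c(spec$low, spec$high) / nyq, type = "pass")
}

# Forward-backward IIR filtering with odd reflective padding: the standard
# filtfilt transient guard of 3 * (filter length - 1) samples per edge,
# shortened for epochs too brief to support it.
filtfilt_refl <- function(flt, x) {
  n <- length(x)
  k <- 3L * (max(length(flt$a), length(flt$b)) - 1L)
  if (k >= n) k <- n - 1L
  if (k > 0L) {
    pre <- 2 * x[1] - x[(k + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - k)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  y <- as.numeric(signal::filter(flt, xp))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(k + 1L):(k + n)]
}

filter_once <- function(flt, x) as.numeric(signal::filter(flt, x))

#' Band-pass filter an epoch set
#'
#' Filters every trial and channel independently; shape, labels and metadata
#' are unchanged.
#'
#' @param epochs An [eeg_epochs] object.
#' @param spec A [filter_spec]; default 5-45 Hz zero-phase Butterworth.
#' @return A filtered [eeg_epochs] object.
#' @export
bandpass <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(spec, "filter_spec"))
  flt <- design_bandpass(spec, epochs$sfreq)
  d <- dim(epochs$data)
  out <- epochs
  apply_fun <- if (spec$zero_phase) filtfilt_refl else filter_once
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out$data[tr, ch, ] <- apply_fun(flt, epochs$data[tr, ch, ])
    }
  }
  out
}
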