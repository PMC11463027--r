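# Core domain types: labelled multichannel epochs, channel subsets, montages,
# and the gzip-JSON session container.

# Canonical 10-10 electrode labels used for case normalization.
.LABELS_1010 <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2"
)

#' Canonicalize electrode names to 10-10 spelling
#'
#' Matches names case-insensitively against the standard 10-10 labels and
#' returns the canonical spelling (e.g. `"fcz"` becomes `"FCz"`). Names not in
#' the 10-10 set are returned unchanged, so synthetic labels like `"CH1"`
#' survive round trips.
#'
#' @param names Character vector of electrode names.
#' @return Character vector of the same length.
#' @export
#' @examples
#' canonical_channels(c("c3", "FCZ", "CH1"))
canonical_channels <- function(names) {
  idx <- match(toupper(names), toupper(.LABELS_1010))
  out <- names
  out[!is.na(idx)] <- .LABELS_1010[idx[!is.na(idx)]]
  out
}

#' The default 16-electrode sensorimotor montage
#'
#' Sixteen 10-10 positions over sensorimotor cortex used as the fixed reduced
#' montage for the B16 baseline and the exhaustive subset search. The set is a
#' package default and can be overridden anywhere a montage is accepted.
#'
#' @return Character vector of 16 channel names.
#' @export
#' @examples
#' montage_16()
montage_16 <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C3", "C1",
    "Cz", "C2", "C4", "CP3", "CP1", "CPz", "CP2", "CP4")
}

#' Construct a labelled set of EEG epochs
#'
#' The universal data container of the package: a `trials x channels x samples`
#' numeric array with per-trial class labels, channel names and sampling rate.
#' Exactly two classes must be present (the pipeline is a two-class method) and
#' the sampling rate must be at least 90 Hz.
#'
#' @param data Numeric array, `trials x channels x samples`. All values finite.
#' @param labels Per-trial class labels (coerced to character); exactly two
#'   distinct values.
#' @param ch_names Channel names, unique after 10-10 canonicalization.
#' @param sfreq Sampling rate in Hz, `>= 90`.
#' @param session_id,subject_id Opaque identifiers.
#' @return An object of class `eeg_epochs`.
#' @export
#' @examples
#' x <- array(rnorm(4 * 2 * 32), c(4, 2, 32))
#' ep <- eeg_epochs(x, c("left", "left", "right", "right"), c("C3", "C4"), 128)
#' ep
eeg_epochs <- function(data, labels, ch_names, sfreq,
                       session_id = "session-1", subject_id = "subject-1") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    validation_error("'data' must be a 3-d array (trials x channels x samples)")
  }
  if (!all(is.finite(data))) {
    validation_error("'data' contains non-finite values")
  }
  d <- dim(data)
  if (d[1] < 1L) validation_error("empty trial axis")
  labels <- as.character(labels)
  if (length(labels) != d[1]) {
    validation_error(sprintf("number of labels (%d) != number of trials (%d)",
                             length(labels), d[1]))
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    validation_error(sprintf("exactly 2 classes required, got %d (%s)",
                             length(classes), paste(classes, collapse = ", ")))
  }
  ch_names <- canonical_channels(as.character(ch_names))
  if (length(ch_names) != d[2]) {
    validation_error(sprintf("%d channel names for %d channels",
                             length(ch_names), d[2]))
  }
  if (anyDuplicated(ch_names)) validation_error("duplicate channel names")
  sfreq <- as.numeric(sfreq)
  if (!is.finite(sfreq) || sfreq < 90) {
    validation_error("sampling rate must be >= 90 Hz")
  }
  structure(
    list(data = data, labels = labels, ch_names = ch_names, sfreq = sfreq,
         session_id = as.character(session_id),
         subject_id = as.character(subject_id)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tab <- table(x$labels)
  cat(sprintf("<eeg_epochs> %s / %s\n", x$subject_id, x$session_id))
  cat(sprintf("  %d trials (%s), %d channels, %d samples @ %g Hz\n",
              d[1], paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              d[2], d[3], x$sfreq))
  cat("  channels:", paste(x$ch_names, collapse = " "), "\n")
  invisible(x)
}

#' Construct a channel subset
#'
#' A validated, ordered set of channel names used to restrict an epoch set.
#'
#' @param names Character vector; non-empty, no duplicates after
#'   canonicalization.
#' @return Character vector of class `channel_subset`.
#' @export
channel_subset <- function(names) {
  names <- canonical_channels(as.character(names))
  if (length(names) < 1L) validation_error("channel subset must be non-empty")
  if (anyDuplicated(names)) validation_error("channel subset has duplicates")
  structure(names, class = c("channel_subset", "character"))
}

# Resolve subset names to channel indices (case-insensitive).
match_channels <- function(names, ch_names) {
  idx <- match(toupper(names), toupper(ch_names))
  if (anyNA(idx)) {
    lookup_error(sprintf("unknown channel name(s): %s",
                         paste(names[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Restrict epochs to a channel subset
#'
#' Returns a new epoch set containing exactly the requested channels, in the
#' requested order; trials, labels and metadata are unchanged. Matching is
#' case-insensitive.
#'
#' @param epochs An [eeg_epochs] object.
#' @param subset Character vector of channel names (or [channel_subset]).
#'   `NULL` keeps all channels.
#' @return An [eeg_epochs] object.
#' @export
subset_channels <- function(epochs, subset) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(subset)) return(epochs)
  subset <- channel_subset(subset)
  idx <- match_channels(subset, epochs$ch_names)
  out <- epochs
  out$data <- epochs$data[, idx, , drop = FALSE]
  out$ch_names <- epochs$ch_names[idx]
  out
}

#' Write a session to a compressed container file
#'
#' Serializes an epoch set as a gzip-compressed JSON document with named
#' fields (`data` plus its dimensions, `labels`, `ch_names`, `sfreq`,
#' identifiers). Metadata round-trips exactly; the data array round-trips as
#' decimal text at near machine precision (relative error below 1e-12).
#'
#' @param epochs An [eeg_epochs] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!all(is.finite(epochs$data))) {
    validation_error("'data' contains non-finite values")
  }
  if (dim(epochs$data)[1] < 1L) validation_error("empty trial axis")
  payload <- list(
    format = "eeg-session/1",
    session_id = epochs$session_id,
    subject_id = epochs$subject_id,
    sfreq = epochs$sfreq,
    ch_names = epochs$ch_names,
    labels = epochs$labels,
    dims = dim(epochs$data),
    data = as.numeric(epochs$data)
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  con <- tryCatch(gzfile(path, "wt"), error = function(e) io_error(conditionMessage(e)))
  ok <- tryCatch({ writeLines(txt, con); TRUE },
                 error = function(e) { close(con); io_error(conditionMessage(e)) })
  close(con)
  invisible(path)
}

#' Read a session container file
#'
#' @param path Path written by [write_session()] (gzip or plain JSON).
#' @return An [eeg_epochs] object.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  obj <- tryCatch(jsonlite::fromJSON(txt),
                  error = function(e) format_error(sprintf("malformed container: %s",
                                                           conditionMessage(e))))
  required <- c("sfreq", "ch_names", "labels", "dims", "data")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    format_error(sprintf("container missing field(s): %s",
                         paste(missing, collapse = ", ")))
  }
  dims <- as.integer(obj$dims)
  if (length(dims) != 3L || length(obj$data) != prod(dims)) {
    format_error("container 'data' length does not match 'dims'")
  }
  eeg_epochs(array(as.numeric(obj$data), dim = dims),
             labels = obj$labels, ch_names = obj$ch_names, sfreq = obj$sfreq,
             session_id = obj$session_id %||% "session-1",
             subject_id = obj$subject_id %||% "subject-1")
}
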