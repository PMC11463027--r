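# Two-class common spatial patterns: class covariances, generalized
# eigendecomposition, spatial filters/patterns, log-variance features.

# Per-trial sample covariance matrices (channels x channels), computed once
# and reused: after filtering, everything downstream (class covariances, CSP,
# log-variance features) depends on the data only through these, and a channel
# subset is just a submatrix.
trial_cov_array <- function(epochs) {
  d <- dim(epochs$data)
  covs <- array(0, c(d[1], d[2], d[2]))
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, , , drop = TRUE]
    if (d[2] == 1L) x <- matrix(x, nrow = 1L)
    xc <- x - rowMeans(x)
    covs[tr, , ] <- tcrossprod(xc) / (d[3] - 1)
  }
  covs
}

# Class-mean covariances from precomputed per-trial covariances restricted to
# channel indices `idx`, for the trials in `rows`.
class_covs_from_trials <- function(covs, labels, rows, idx, shrinkage = 0,
                                   ch_names = NULL) {
  classes <- sort(unique(labels[rows]))
  if (length(classes) != 2L) validation_error("need exactly 2 classes")
  n_ch <- length(idx)
  avg <- lapply(classes, function(cl) {
    tr <- rows[labels[rows] == cl]
    if (length(tr) < 2L) {
      validation_error(sprintf("class '%s' has fewer than 2 trials", cl))
    }
    s <- matrix(0, n_ch, n_ch)
    for (i in tr) {
      ci <- covs[i, idx, idx, drop = TRUE]
      s <- s + ci / sum(diag(ci))
    }
    s / length(tr)
  })
  if (shrinkage > 0) {
    tgt <- diag(n_ch) / n_ch  # trace-normalized covariances have trace 1
    avg <- lapply(avg, function(s) (1 - shrinkage) * s + shrinkage * tgt)
  }
  structure(list(sigma1 = avg[[1]], sigma2 = avg[[2]], class_order = classes,
                 ch_names = ch_names, shrinkage = shrinkage),
            class = "class_covs")
}

#' Class-mean covariance matrices of a two-class epoch set
#'
#' Per trial, the sample covariance over the time axis is computed and
#' trace-normalized; the normalized matrices are averaged within each class
#' (classes in sorted label order), then optionally shrunk toward
#' `(trace / n_channels) * identity`.
#'
#' @param epochs An [eeg_epochs] object with at least 2 trials per class.
#' @param shrinkage Shrinkage fraction in `[0, 1]` toward the scaled identity.
#' @return An object of class `class_covs` with fields `sigma1`, `sigma2`,
#'   `class_order`, `ch_names`.
#' @export
class_covariances <- function(epochs, shrinkage = 0) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[3] <= 1L) validation_error("need more than 1 sample per trial")
  if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1) {
    validation_error("'shrinkage' must be in [0, 1]")
  }
  covs <- trial_cov_array(epochs)
  class_covs_from_trials(covs, epochs$labels, seq_along(epochs$labels),
                         seq_along(epochs$ch_names), shrinkage,
                         ch_names = epochs$ch_names)
}

#' Construct class covariances from explicit matrices
#'
#' Mainly for testing CSP against analytically known covariance pairs. Both
#' matrices are symmetrized and trace-normalized.
#'
#' @param sigma1,sigma2 Symmetric positive semi-definite matrices of equal
#'   dimension.
#' @param ch_names Optional channel names.
#' @param class_order Labels mapped to `sigma1`/`sigma2`.
#' @return A `class_covs` object.
#' @export
class_covs <- function(sigma1, sigma2, ch_names = NULL,
                       class_order = c("left", "right")) {
  sigma1 <- as.matrix(sigma1); sigma2 <- as.matrix(sigma2)
  if (!identical(dim(sigma1), dim(sigma2)) || nrow(sigma1) != ncol(sigma1)) {
    validation_error("'sigma1' and 'sigma2' must be square of equal dimension")
  }
  if (max(abs(sigma1 - t(sigma1))) > 1e-8 || max(abs(sigma2 - t(sigma2))) > 1e-8) {
    validation_error("covariance matrices must be symmetric")
  }
  sigma1 <- (sigma1 + t(sigma1)) / 2
  sigma2 <- (sigma2 + t(sigma2)) / 2
  if (min(eigen(sigma1, symmetric = TRUE, only.values = TRUE)$values) < -1e-10 ||
      min(eigen(sigma2, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    validation_error("covariance matrices must be positive semi-definite")
  }
  structure(list(sigma1 = sigma1 / sum(diag(sigma1)),
                 sigma2 = sigma2 / sum(diag(sigma2)),
                 class_order = class_order,
                 ch_names = ch_names %||% sprintf("CH%02d", seq_len(nrow(sigma1))),
                 shrinkage = 0),
            class = "class_covs")
}

#' Fit a two-class CSP decomposition
#'
#' Solves the generalized eigenproblem `sigma1 w = lambda (sigma1 + sigma2) w`
#' by whitening the composite covariance. Eigenvalues lie in `[0, 1]`;
#' components are ordered by discriminability `max(lambda, 1 - lambda)`
#' descending (interleaving the two eigenvalue extremes) unless
#' `ordering = "eigenvalue"` requests plain descending order. Patterns are the
#' corresponding columns of the inverse of the full filter matrix — the mixing
#' directions describing how each source projects onto the electrodes. Each
#' filter is sign-fixed so its largest-magnitude coefficient is positive
#' (the matched pattern is flipped with it), making fits deterministic.
#'
#' @param covs A `class_covs` object (see [class_covariances()]).
#' @param n_components Number of components to retain (`<=` channel count).
#' @param ordering `"discriminability"` (default) or `"eigenvalue"`.
#' @return An object of class `csp_model` with `filters` and `patterns`
#'   (`n_components x n_channels` matrices, one component per row), `eigvals`,
#'   `ch_names` and `n_components`.
#' @export
fit_csp <- function(covs, n_components = 8,
                    ordering = c("discriminability", "eigenvalue")) {
  stopifnot(inherits(covs, "class_covs"))
  ordering <- match.arg(ordering)
  n_ch <- nrow(covs$sigma1)
  if (!is_count(n_components, 1L) || n_components > n_ch) {
    validation_error(sprintf("'n_components' must be in 1..%d", n_ch))
  }
  # tiny relative identity floor: guards exact rank deficiency while
  # perturbing eigenvalues by O(1e-12) only
  composite <- covs$sigma1 + covs$sigma2
  composite <- composite + (1e-12 * mean(diag(composite))) * diag(n_ch)
  ec <- eigen(composite, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(ec$values)) {
    numerical_error(paste("composite covariance is numerically singular;",
                          "refit with shrinkage > 0"))
  }
  whitener <- diag(1 / sqrt(ec$values), n_ch) %*% t(ec$vectors)
  s1w <- whitener %*% covs$sigma1 %*% t(whitener)
  s1w <- (s1w + t(s1w)) / 2
  es <- eigen(s1w, symmetric = TRUE)
  lambda <- pmin(pmax(es$values, 0), 1)
  filters_full <- t(es$vectors) %*% whitener   # rows are filters

  # discriminability compared at 1e-8 resolution so that exact ties (e.g. a
  # lambda, 1 - lambda pair) are broken by eigenvalue, not by float noise
  ord <- switch(ordering,
    discriminability = order(-round(pmax(lambda, 1 - lambda), 8), -lambda),
    eigenvalue = order(-lambda))
  lambda <- lambda[ord]
  filters_full <- filters_full[ord, , drop = FALSE]
  patterns_full <- solve(filters_full)         # columns are patterns

  # Sign convention: largest-|coefficient| of each filter positive.
  for (j in seq_len(n_ch)) {
    w <- filters_full[j, ]
    if (w[which.max(abs(w))] < 0) {
      filters_full[j, ] <- -w
      patterns_full[, j] <- -patterns_full[, j]
    }
  }

  keep <- seq_len(n_components)
  ch <- covs$ch_names %||% sprintf("CH%02d", seq_len(n_ch))
  filters <- filters_full[keep, , drop = FALSE]
  patterns <- t(patterns_full[, keep, drop = FALSE])
  dimnames(filters) <- dimnames(patterns) <-
    list(sprintf("CSP%d", keep), ch)
  structure(list(filters = filters, patterns = patterns,
                 eigvals = lambda[keep], ch_names = ch,
                 n_components = as.integer(n_components),
                 class_order = covs$class_order),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d components over %d channels\n",
              x$n_components, length(x$ch_names)))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigvals), collapse = " "), "\n")
  cat(sprintf("  class order: %s\n", paste(x$class_order, collapse = " vs ")))
  invisible(x)
}

#' @export
coef.csp_model <- function(object, ...) object$filters

#' Log-variance CSP features
#'
#' Projects every trial through the model's spatial filters and returns, per
#' trial and component, the natural log of the variance of the filtered time
#' course.
#'
#' @param model A `csp_model` from [fit_csp()].
#' @param epochs An [eeg_epochs] object with exactly the model's channels in
#'   the model's order.
#' @return Numeric matrix, `n_trials x n_components`.
#' @export
apply_csp <- function(model, epochs) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "eeg_epochs"))
  if (!identical(toupper(epochs$ch_names), toupper(model$ch_names))) {
    validation_error(sprintf(
      "channel mismatch; model lacks [%s], epochs lack [%s]",
      paste(setdiff(toupper(epochs$ch_names), toupper(model$ch_names)), collapse = ", "),
      paste(setdiff(toupper(model$ch_names), toupper(epochs$ch_names)), collapse = ", ")))
  }
  covs <- trial_cov_array(epochs)
  csp_features_from_covs(model, covs, seq_len(dim(covs)[1]),
                         seq_along(model$ch_names))
}

# Features from precomputed trial covariances: log diag(W C W').
csp_features_from_covs <- function(model, covs, rows, idx) {
  W <- model$filters[, , drop = FALSE]
  out <- matrix(0, length(rows), nrow(W))
  for (k in seq_along(rows)) {
    C <- covs[rows[k], idx, idx, drop = TRUE]
    out[k, ] <- log(rowSums((W %*% C) * W))
  }
  colnames(out) <- rownames(W)
  out
}
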