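# Two-class Fisher discriminant with pooled within-class covariance and equal
# priors, fit directly on CSP log-variance features.

lda_fit <- function(x, y) {
  classes <- sort(unique(y))
  if (length(classes) != 2L) validation_error("LDA needs exactly 2 classes")
  x1 <- x[y == classes[1], , drop = FALSE]
  x2 <- x[y == classes[2], , drop = FALSE]
  if (nrow(x1) < 2L || nrow(x2) < 2L) {
    validation_error("each class needs >= 2 training trials")
  }
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  sw <- ((nrow(x1) - 1) * stats::cov(x1) + (nrow(x2) - 1) * stats::cov(x2)) /
    (nrow(x1) + nrow(x2) - 2)
  # tiny ridge guards exactly collinear features without changing the solution
  sw <- sw + diag(1e-10 * (mean(diag(sw)) + 1e-300), ncol(x))
  w <- solve(sw, m1 - m2)
  list(w = w, bias = sum(w * (m1 + m2)) / 2, classes = classes)
}

# Decision rule: first class (sorted order) when the score is on or above the
# boundary — ties resolve to the first class deterministically.
lda_predict <- function(fit, x) {
  s <- drop(x %*% fit$w) - fit$bias
  ifelse(s >= 0, fit$classes[1], fit$classes[2])
}
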