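# Bayesian A/B evaluation of pipeline variants: beta-binomial posteriors over
# per-trial correctness pooled across subjects, and Monte-Carlo ratio sampling
# against the full-electrode baseline.

#' Beta prior on a variant's accuracy
#'
#' The default `Beta(6, 4)` encodes the prior belief that variants perform
#' better than chance; with the trial counts typically pooled its influence is
#' marginal.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_prior`.
#' @export
beta_prior <- function(alpha = 6, beta = 4) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0) {
    validation_error("'alpha' and 'beta' must be > 0")
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' Beta posterior from pooled classification results
#'
#' Pools correct/incorrect trial counts over all supplied results (dichotomic
#' data) and performs the conjugate update: `alpha + successes`,
#' `beta + failures`.
#'
#' @param results An `accuracy_result` or non-empty list of them, typically
#'   one per subject.
#' @param prior A [beta_prior].
#' @return An object of class `beta_posterior` with fields `alpha`, `beta`,
#'   `successes`, `failures`.
#' @export
posterior_from_results <- function(results, prior = beta_prior()) {
  stopifnot(inherits(prior, "beta_prior"))
  if (inherits(results, "accuracy_result")) results <- list(results)
  if (!length(results)) validation_error("'results' must be non-empty")
  if (!all(vapply(results, inherits, logical(1), "accuracy_result"))) {
    validation_error("'results' must contain accuracy_result objects")
  }
  successes <- sum(vapply(results, `[[`, numeric(1), "correct"))
  failures <- sum(vapply(results, `[[`, numeric(1), "total")) - successes
  structure(list(alpha = prior$alpha + successes, beta = prior$beta + failures,
                 successes = successes, failures = failures, prior = prior),
            class = "beta_posterior")
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("<beta_posterior> Beta(%g, %g) from %d/%d pooled trials\n",
              x$alpha, x$beta, x$successes, x$successes + x$failures))
  invisible(x)
}

#' Monte-Carlo improvement of a variant over the baseline
#'
#' Draws `n_draws` independent pairs `(a, b)` from the variant and baseline
#' posteriors and summarizes the fractions `a / b`: their mean, the percentual
#' improvement `100 * (mean - 1)`, and a central 95% credible interval (an
#' extension beyond the ratio summary, reported because it costs nothing).
#'
#' Note the estimator's self-comparison bias: for independent draws from
#' identical posteriors `E[a/b] = E[a] * E[1/b] > 1`. This property of the
#' ratio-of-independent-draws evaluation is preserved, not corrected.
#'
#' @param variant,baseline `beta_posterior` objects. `baseline$alpha` must
#'   exceed 1 for the mean of `1/b` to be finite; otherwise a divergence
#'   warning is raised.
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed; summaries are reproducible bit-for-bit.
#' @return An object of class `improvement_summary` with `mean_fraction`,
#'   `pct_improvement`, `credible_interval`, `mc_se`, `n_draws`, `seed`.
#' @export
mc_improvement <- function(variant, baseline, n_draws = 10000, seed = 42L) {
  stopifnot(inherits(variant, "beta_posterior"),
            inherits(baseline, "beta_posterior"))
  if (!is_count(n_draws, 1L)) validation_error("'n_draws' must be >= 1")
  if (baseline$alpha <= 1) {
    warning(warningCondition(
      "baseline posterior alpha <= 1: mean of the reciprocal diverges",
      class = "cspselect_divergence_warning"))
  }
  fractions <- with_seed(seed, {
    a <- stats::rbeta(n_draws, variant$alpha, variant$beta)
    b <- stats::rbeta(n_draws, baseline$alpha, baseline$beta)
    a / b
  })
  m <- mean(fractions)
  structure(list(mean_fraction = m,
                 pct_improvement = 100 * (m - 1),
                 credible_interval = unname(stats::quantile(fractions, c(0.025, 0.975))),
                 mc_se = stats::sd(fractions) / sqrt(n_draws),
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "improvement_summary")
}

#' @export
print.improvement_summary <- function(x, ...) {
  cat(sprintf("<improvement_summary> %+.2f%% vs baseline (mean fraction %.4f, 95%% CI [%.3f, %.3f], %d draws)\n",
              x$pct_improvement, x$mean_fraction,
              x$credible_interval[1], x$credible_interval[2], x$n_draws))
  invisible(x)
}

#' Evaluate all variants against the full-electrode baseline
#'
#' Builds one pooled beta posterior per variant and for the baseline, then
#' Monte-Carlo ratio summaries of each variant against the baseline. If
#' `comb_from` names variants, an additional `"Comb"` variant is formed by
#' taking, per subject, the result with the highest accuracy across those
#' variants' results. Per-variant Monte-Carlo seeds are derived from `seed`
#' and the sorted variant names, so insertion order does not affect any
#' summary.
#'
#' @param variant_results Named list; each element is a list of
#'   `accuracy_result`s, one per subject (same subject coverage everywhere).
#' @param baseline_results List of the baseline's `accuracy_result`s, one per
#'   subject.
#' @param prior A [beta_prior].
#' @param n_draws,seed Monte-Carlo settings.
#' @param comb_from Optional character vector of variant names pooled into the
#'   `"Comb"` per-subject-best variant.
#' @return Named list of `improvement_summary` objects, with the posteriors
#'   attached as attribute `"posteriors"`.
#' @export
evaluate_variants <- function(variant_results, baseline_results,
                              prior = beta_prior(), n_draws = 10000,
                              seed = 42L, comb_from = NULL) {
  if (!length(variant_results) || is.null(names(variant_results)) ||
      any(names(variant_results) == "")) {
    validation_error("'variant_results' must be a non-empty named list")
  }
  n_sub <- length(baseline_results)
  if (!n_sub) validation_error("'baseline_results' must be non-empty")
  bad <- names(variant_results)[vapply(variant_results, length, integer(1)) != n_sub]
  if (length(bad)) {
    validation_error(sprintf("subject coverage mismatch for variant(s): %s",
                             paste(bad, collapse = ", ")))
  }

  if (!is.null(comb_from)) {
    missing <- setdiff(comb_from, names(variant_results))
    if (length(missing)) {
      validation_error(sprintf("'comb_from' names unknown variant(s): %s",
                               paste(missing, collapse = ", ")))
    }
    comb <- lapply(seq_len(n_sub), function(i) {
      pool <- lapply(comb_from, function(v) variant_results[[v]][[i]])
      acc <- vapply(pool, `[[`, numeric(1), "mean_accuracy")
      corr <- vapply(pool, `[[`, numeric(1), "correct")
      pool[[order(-acc, -corr)[1]]]
    })
    variant_results$Comb <- comb
  }

  baseline_post <- posterior_from_results(baseline_results, prior)
  posteriors <- lapply(variant_results, posterior_from_results, prior = prior)
  nm_sorted <- sort(names(variant_results))
  summaries <- lapply(names(variant_results), function(nm) {
    mc_improvement(posteriors[[nm]], baseline_post, n_draws,
                   seed = derive_seed(seed, match(nm, nm_sorted)))
  })
  names(summaries) <- names(variant_results)
  attr(summaries, "posteriors") <- c(list(BFull = baseline_post), posteriors)
  summaries
}

#' Beta density table for plotting variant posteriors
#'
#' @param posteriors Named list of `beta_posterior` objects.
#' @param grid Evaluation points, strictly inside `(0, 1)`.
#' @return Long-format `data.frame` with columns `posterior`, `x`, `density`.
#' @export
posterior_density_table <- function(posteriors, grid) {
  if (inherits(posteriors, "beta_posterior")) posteriors <- list(posteriors)
  if (!is.numeric(grid) || any(grid <= 0) || any(grid >= 1)) {
    domain_error("'grid' points must lie strictly inside (0, 1)")
  }
  nm <- names(posteriors) %||% sprintf("posterior%d", seq_along(posteriors))
  do.call(rbind, lapply(seq_along(posteriors), function(i) {
    data.frame(posterior = nm[i], x = grid,
               density = stats::dbeta(grid, posteriors[[i]]$alpha,
                                      posteriors[[i]]$beta),
               stringsAsFactors = FALSE)
  }))
}
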