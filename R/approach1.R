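# Exhaustive electrode-subset search with one-sided t-test selection across
# subjects.

#' Enumerate all channel subsets of at least a minimum size
#'
#' Subsets are returned in canonical order: by size ascending, then
#' lexicographically by channel index within the montage. Each subset keeps
#' montage order.
#'
#' @param montage Character vector of channel names.
#' @param min_size Minimum subset size, in `1..length(montage)`.
#' @return List of [channel_subset] vectors.
#' @export
#' @examples
#' length(enumerate_subsets(montage_16(), 14))
enumerate_subsets <- function(montage, min_size) {
  montage <- channel_subset(montage)
  n <- length(montage)
  if (!is_count(min_size, 1L) || min_size > n) {
    validation_error(sprintf("'min_size' must be in 1..%d", n))
  }
  out <- list()
  for (k in seq(min_size, n)) {
    cols <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cols)),
                         function(j) channel_subset(montage[cols[, j]])))
  }
  out
}

#' One-sided one-sample t-test for a positive mean
#'
#' Tests `H0: mu <= 0` against `Ha: mu > 0` for a sample of percentage
#' changes: `t = mean / (sd / sqrt(n))` with the sample (n-1) standard
#' deviation, upper-tail p from the t distribution with `n - 1` degrees of
#' freedom. A zero-variance sample is degenerate: p is 0 when the common value
#' is positive and 1 otherwise.
#'
#' @param changes Numeric vector, length `>= 2`.
#' @return The one-sided p-value.
#' @export
#' @examples
#' one_sided_ttest(c(1, 2, 3))
one_sided_ttest <- function(changes) {
  if (!is.numeric(changes) || length(changes) < 2L) {
    validation_error("need >= 2 values")
  }
  s <- stats::sd(changes)
  if (s == 0) return(if (changes[1] > 0) 0 else 1)
  tstat <- mean(changes) / (s / sqrt(length(changes)))
  stats::pt(tstat, df = length(changes) - 1L, lower.tail = FALSE)
}

combination_result <- function(subset, pct_changes, alpha) {
  p <- one_sided_ttest(pct_changes)
  structure(list(subset = subset,
                 per_subject_pct_change = pct_changes,
                 mean_pct_change = mean(pct_changes),
                 p_value = p,
                 significant = p < alpha),
            class = "combination_result")
}

#' Exhaustive subset search across a cohort of subjects
#'
#' For every subset of the montage with at least `min_size` channels, computes
#' each subject's cross-validated accuracy and its percentage change against
#' that subject's fixed-montage baseline, then tests whether the mean change is
#' significantly positive across subjects (one-sided one-sample t-test at
#' `alpha`, no multiple-testing correction — each combination is tested at the
#' nominal level; set `adjust = TRUE` for an additional Benjamini-Hochberg
#' column, a deviation from the reference procedure).
#'
#' Per-subject baselines are computed once; subsets are evaluated from cached
#' per-trial covariance matrices, which is algebraically identical to
#' re-running the full pipeline per subset.
#'
#' @param sessions List of [eeg_epochs], one per subject.
#' @param montage Montage to enumerate over (all sessions must contain it).
#' @param min_size Minimal subset size (default 8).
#' @param cv A [cv_config]; the same folds are reused for every subset of a
#'   subject.
#' @param filter A [filter_spec] or `NULL`.
#' @param n_components CSP components, capped at each subset's size (the
#'   feature count follows the electrode count once a subset is smaller than
#'   the requested depth, mirroring the full-scale design where the minimum
#'   subset size is chosen to support the full feature count). Default 8.
#' @param alpha Significance level (default 0.05).
#' @param shrinkage Covariance shrinkage fraction.
#' @param adjust Add Benjamini-Hochberg adjusted p-values (off by default).
#' @return An object of class `combination_search` — a list of
#'   `combination_result`s in canonical subset order, with the per-subject
#'   baselines attached; convert with [as.data.frame()].
#' @export
search_combinations <- function(sessions, montage = montage_16(), min_size = 8,
                                cv = cv_config(), filter = filter_spec(),
                                n_components = NULL, alpha = 0.05,
                                shrinkage = 0, adjust = FALSE) {
  if (!length(sessions)) validation_error("'sessions' must be non-empty")
  montage <- channel_subset(montage)
  n_components <- n_components %||% 8L
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    validation_error("'alpha' must be in (0, 1)")
  }
  subsets <- enumerate_subsets(montage, min_size)

  per_subject <- lapply(sessions, function(ep) {
    filtered <- if (is.null(filter)) ep else bandpass(ep, filter)
    msub <- subset_channels(filtered, montage)
    covs <- trial_cov_array(msub)
    folds <- make_folds(msub$labels, cv)
    base <- crossval_from_covs(covs, msub$labels, folds,
                               seq_along(msub$ch_names),
                               min(n_components, length(montage)),
                               shrinkage, subset_names = msub$ch_names)
    list(covs = covs, labels = msub$labels, folds = folds,
         ch_names = msub$ch_names, baseline = base)
  })

  results <- lapply(subsets, function(sub) {
    pct <- vapply(per_subject, function(ps) {
      idx <- match_channels(sub, ps$ch_names)
      acc <- crossval_from_covs(ps$covs, ps$labels, ps$folds, idx,
                                min(n_components, length(idx)), shrinkage,
                                subset_names = sub)$mean_accuracy
      percentage_change(acc, ps$baseline$mean_accuracy)
    }, numeric(1))
    combination_result(sub, pct, alpha)
  })

  if (adjust) {
    padj <- stats::p.adjust(vapply(results, `[[`, numeric(1), "p_value"), "BH")
    for (i in seq_along(results)) results[[i]]$p_adjusted <- padj[i]
  }
  structure(results,
            class = "combination_search",
            alpha = alpha,
            baselines = lapply(per_subject, `[[`, "baseline"))
}

#' @export
as.data.frame.combination_search <- function(x, ...) {
  n_sub <- length(x[[1]]$per_subject_pct_change)
  pct <- t(vapply(x, `[[`, numeric(n_sub), "per_subject_pct_change"))
  colnames(pct) <- sprintf("pct_change_s%d", seq_len(n_sub))
  df <- data.frame(
    subset = vapply(x, function(r) paste(r$subset, collapse = "+"), character(1)),
    size = vapply(x, function(r) length(r$subset), integer(1)),
    pct,
    mean_pct_change = vapply(x, `[[`, numeric(1), "mean_pct_change"),
    p_value = vapply(x, `[[`, numeric(1), "p_value"),
    significant = vapply(x, `[[`, logical(1), "significant"),
    stringsAsFactors = FALSE
  )
  if (!is.null(x[[1]]$p_adjusted)) {
    df$p_adjusted <- vapply(x, `[[`, numeric(1), "p_adjusted")
  }
  df
}

#' @export
print.combination_search <- function(x, ...) {
  cat(sprintf("<combination_search> %d subsets, %d flagged significant at alpha = %g\n",
              length(x), sum(vapply(x, `[[`, logical(1), "significant")),
              attr(x, "alpha")))
  invisible(x)
}

# Canonical order of candidate subsets relative to a reference channel order:
# size ascending, then lexicographic by channel index.
canonical_subset_order <- function(candidates, reference) {
  keys <- vapply(candidates, function(s) {
    idx <- match(toupper(s), toupper(reference))
    paste(sprintf("%03d", sort(idx)), collapse = "")
  }, character(1))
  sizes <- lengths(candidates)
  order(sizes, keys)
}

#' Best candidate subset for a single subject
#'
#' Evaluates each candidate with the cross-validated pipeline on the session
#' and returns the one with maximal mean accuracy. Ties resolve to fewer
#' electrodes, then canonical order. Duplicate candidates are collapsed first.
#'
#' @param candidates Non-empty list of channel subsets.
#' @param session An [eeg_epochs] session.
#' @param cv,filter,n_components,shrinkage Pipeline settings; `n_components`
#'   is capped at each candidate's size.
#' @return List with elements `subset` (the winner) and `result` (its
#'   `accuracy_result`).
#' @export
best_per_subject <- function(candidates, session, cv = cv_config(),
                             filter = filter_spec(), n_components = 8,
                             shrinkage = 0) {
  if (!length(candidates)) validation_error("'candidates' must be non-empty")
  candidates <- lapply(candidates, channel_subset)
  keys <- vapply(candidates, function(s) paste(sort(toupper(s)), collapse = "|"),
                 character(1))
  candidates <- candidates[!duplicated(keys)]
  candidates <- candidates[canonical_subset_order(candidates, session$ch_names)]

  filtered <- if (is.null(filter)) session else bandpass(session, filter)
  results <- lapply(candidates, function(sub) {
    crossval_accuracy(filtered, sub, cv = cv, filter = NULL,
                      n_components = min(n_components, length(sub)),
                      shrinkage = shrinkage)
  })
  acc <- vapply(results, `[[`, numeric(1), "mean_accuracy")
  best <- which(acc == max(acc))[1]  # candidates pre-sorted: size, canonical
  list(subset = candidates[[best]], result = results[[best]])
}
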