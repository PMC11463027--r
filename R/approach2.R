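# Pattern-threshold electrode extraction: channels whose CSP-pattern value
# deviates from the pattern mean by more than theta standard deviations are
# selected, per cross-validation split, and the resulting combinations are
# evaluated to pick the best one.

#' Electrode-selection configuration
#'
#' @param theta Threshold multiplier on the pattern standard deviation
#'   (default 1.5).
#' @param n_patterns Number of leading CSP patterns inspected (default 8; the
#'   later components are the least discriminative).
#' @param min_electrodes Minimal combination size kept for evaluation
#'   (default 3, i.e. "more than 2 electrodes").
#' @param sd_convention `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1) for the pattern standard deviation.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(theta = 1.5, n_patterns = 8, min_electrodes = 3,
                             sd_convention = c("population", "sample")) {
  if (!is.numeric(theta) || theta <= 0) validation_error("'theta' must be > 0")
  if (!is_count(n_patterns, 1L)) validation_error("'n_patterns' must be >= 1")
  if (!is_count(min_electrodes, 1L)) validation_error("'min_electrodes' must be >= 1")
  structure(list(theta = theta, n_patterns = as.integer(n_patterns),
                 min_electrodes = as.integer(min_electrodes),
                 sd_convention = match.arg(sd_convention)),
            class = "selection_config")
}

pattern_sd <- function(p, convention) {
  if (convention == "population") sqrt(mean((p - mean(p))^2)) else stats::sd(p)
}

#' Select electrodes from one CSP pattern
#'
#' Returns the channels whose pattern value deviates from the mean of all
#' pattern values by strictly more than `theta` standard deviations:
#' `|e_p - mean(p)| > theta * sd(p)`. A constant pattern selects nothing. The
#' selection is invariant to affine transforms of the pattern.
#'
#' @param p Named numeric pattern vector (names are channels), length `>= 2`.
#' @param theta Threshold multiplier.
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return Character vector of selected channel names (possibly empty).
#' @export
#' @examples
#' select_electrodes_from_pattern(c(C3 = 0, Cz = 0, CP3 = 0, C4 = 10))
select_electrodes_from_pattern <- function(p, theta = 1.5,
                                           sd_convention = c("population", "sample")) {
  if (!is.numeric(p) || length(p) < 2L) {
    validation_error("pattern must have >= 2 electrode values")
  }
  if (is.null(names(p))) names(p) <- sprintf("CH%02d", seq_along(p))
  sd_convention <- match.arg(sd_convention)
  s <- pattern_sd(p, sd_convention)
  names(p)[abs(p - mean(p)) > theta * s]
}

#' Extract an electrode combination from a fitted CSP model
#'
#' Applies the pattern-threshold rule to each of the first
#' `min(n_patterns, n_components)` patterns and returns the union of the
#' selections, ordered as in the model's channel list.
#'
#' @param model A `csp_model` from [fit_csp()].
#' @param cfg A [selection_config].
#' @return Character vector of channel names in model channel order; may be
#'   empty (callers must handle the degenerate all-constant case).
#' @export
extract_combination <- function(model, cfg = selection_config()) {
  stopifnot(inherits(model, "csp_model"), inherits(cfg, "selection_config"))
  k <- min(cfg$n_patterns, model$n_components)
  selected <- character(0)
  for (j in seq_len(k)) {
    p <- model$patterns[j, ]
    names(p) <- model$ch_names
    selected <- union(selected,
                      select_electrodes_from_pattern(p, cfg$theta,
                                                     cfg$sd_convention))
  }
  model$ch_names[model$ch_names %in% selected]
}

#' Per-split extraction and best-combination selection
#'
#' The complete pattern-threshold procedure on one session: for every
#' cross-validation split, fit CSP on the split's training trials over the
#' base channel set and extract a combination; deduplicate the combinations,
#' discard those smaller than `cfg$min_electrodes`, evaluate each survivor
#' with the cross-validated pipeline (same folds), and return the best by mean
#' accuracy (ties: fewer electrodes, then canonical order).
#'
#' The candidate evaluation reuses the session that produced the candidates,
#' as the reference procedure does; use [transfer_accuracy()] for an unbiased
#' cross-session check. `n_components` is capped at each candidate's size
#' during evaluation.
#'
#' @param session An [eeg_epochs] session.
#' @param cv A [cv_config]; extraction and evaluation share its folds.
#' @param filter A [filter_spec] or `NULL`.
#' @param n_components CSP components for extraction and evaluation.
#' @param cfg A [selection_config].
#' @param base Channel set fed to the extraction CSP: `NULL` for all channels
#'   of the session (full base) or a montage such as [montage_16()].
#' @param shrinkage Covariance shrinkage fraction.
#' @return An object of class `approach2_result`: list with `best` (winning
#'   subset or `NULL`), `best_result` (its `accuracy_result` or `NULL`),
#'   `candidates` (all deduplicated, size-filtered subsets),
#'   `candidate_results`, and `empty` (`TRUE` when every extracted combination
#'   was discarded — the empty-candidate signal; callers fall back to a
#'   baseline).
#' @export
approach2_best <- function(session, cv = cv_config(), filter = filter_spec(),
                           n_components = 8, cfg = selection_config(),
                           base = NULL, shrinkage = 0) {
  stopifnot(inherits(session, "eeg_epochs"))
  filtered <- if (is.null(filter)) session else bandpass(session, filter)
  base_names <- if (is.null(base)) filtered$ch_names else channel_subset(base)
  bsub <- subset_channels(filtered, base_names)
  n_comp_base <- min(n_components, length(bsub$ch_names))

  covs <- trial_cov_array(bsub)
  folds <- make_folds(bsub$labels, cv)
  combos <- lapply(seq_len(max(folds)), function(f) {
    train <- which(folds != f)
    ccovs <- class_covs_from_trials(covs, bsub$labels, train,
                                    seq_along(bsub$ch_names), shrinkage,
                                    ch_names = bsub$ch_names)
    extract_combination(fit_csp(ccovs, n_comp_base), cfg)
  })

  keys <- vapply(combos, function(s) paste(sort(toupper(s)), collapse = "|"),
                 character(1))
  combos <- combos[!duplicated(keys)]
  combos <- combos[lengths(combos) >= cfg$min_electrodes]
  if (!length(combos)) {
    return(structure(list(best = NULL, best_result = NULL,
                          candidates = list(), candidate_results = list(),
                          empty = TRUE),
                     class = "approach2_result"))
  }
  combos <- combos[canonical_subset_order(combos, session$ch_names)]

  results <- lapply(combos, function(sub) {
    crossval_accuracy(filtered, sub, cv = cv, filter = NULL,
                      n_components = min(n_components, length(sub)),
                      shrinkage = shrinkage)
  })
  acc <- vapply(results, `[[`, numeric(1), "mean_accuracy")
  best <- which(acc == max(acc))[1]
  structure(list(best = combos[[best]], best_result = results[[best]],
                 candidates = combos, candidate_results = results,
                 empty = FALSE),
            class = "approach2_result")
}

#' @export
print.approach2_result <- function(x, ...) {
  if (x$empty) {
    cat("<approach2_result> no candidate with enough electrodes\n")
  } else {
    cat(sprintf("<approach2_result> %d candidate(s); best accuracy %.3f\n",
                length(x$candidates), x$best_result$mean_accuracy))
    cat("  best:", paste(x$best, collapse = " "), "\n")
  }
  invisible(x)
}
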