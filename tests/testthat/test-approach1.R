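test_that("subset enumeration is complete and canonically ordered", {
  m3 <- c("C3", "Cz", "C4")
  subs <- enumerate_subsets(m3, 2)
  expect_length(subs, 4)
  expect_identical(lapply(subs, as.character),
                   list(c("C3", "Cz"), c("C3", "C4"), c("Cz", "C4"),
                        c("C3", "Cz", "C4")))
  expect_length(enumerate_subsets(montage_16(), 16), 1)
  # binomial-sum oracle on the full-scale enumeration
  expect_length(enumerate_subsets(montage_16(), 8),
                sum(choose(16, 8:16)))
  expect_error(enumerate_subsets(m3, 0), class = "cspselect_validation_error")
  expect_error(enumerate_subsets(m3, 4), class = "cspselect_validation_error")
})

test_that("the one-sided t-test matches the t-distribution tail", {
  # frozen from the t CDF: t = mean/(sd/sqrt(n)) = 3.4641, df = 2
  expect_equal(one_sided_ttest(c(1, 2, 3)), 0.03708995, tolerance = 1e-6)
  expect_equal(one_sided_ttest(c(-1, -2, -3)), 1 - 0.03708995, tolerance = 1e-6)
  expect_equal(one_sided_ttest(c(-2, -1, 0, 1, 2)), 0.5)
  # agrees with the reference implementation
  x <- c(0.3, -1.2, 2.5, 0.7, 1.1)
  expect_equal(one_sided_ttest(x),
               t.test(x, alternative = "greater")$p.value, tolerance = 1e-12)
  # degenerate zero-variance samples
  expect_identical(one_sided_ttest(c(2, 2, 2)), 0)
  expect_identical(one_sided_ttest(c(-2, -2, -2)), 1)
  expect_identical(one_sided_ttest(c(0, 0)), 1)
  expect_error(one_sided_ttest(5), class = "cspselect_validation_error")
  # monotone evidence: a constant shift upward strictly decreases p
  base <- c(-1, 0.5, 2, 1)
  expect_lt(one_sided_ttest(base + 1), one_sided_ttest(base))
})

test_that("a search over the full montage only centers on zero change", {
  sessions <- lapply(1:3, function(s)
    quick_session(seed = s, n_ch = 4, n_trials = 15, effect = 2))
  montage <- sessions[[1]]$ch_names
  res <- search_combinations(sessions, montage = montage, min_size = 4,
                             n_components = 4)
  expect_length(res, 1)
  # the lone subset is the baseline itself: all pct changes are exactly 0
  expect_identical(res[[1]]$per_subject_pct_change, rep(0, 3))
  expect_identical(res[[1]]$p_value, 1)
  expect_false(res[[1]]$significant)
})

test_that("search results are deterministic, tabular and definitional", {
  sessions <- lapply(1:3, function(s)
    quick_session(seed = 10 + s, n_ch = 5, n_trials = 15, effect = 4,
                  disc = c("C3", "C4")))
  montage <- sessions[[1]]$ch_names
  res <- search_combinations(sessions, montage = montage, min_size = 4,
                             n_components = 3)
  expect_length(res, choose(5, 4) + 1)
  res2 <- search_combinations(sessions, montage = montage, min_size = 4,
                              n_components = 3)
  expect_equal(res, res2, ignore_attr = TRUE)
  # single-subset significance equals the t-test of its pct changes
  r <- res[[2]]
  expect_identical(r$p_value, one_sided_ttest(r$per_subject_pct_change))
  df <- as.data.frame(res)
  expect_identical(nrow(df), length(res))
  expect_true(all(c("subset", "mean_pct_change", "p_value", "significant")
                  %in% names(df)))
  # optional multiple-testing column is off by default
  expect_null(res[[1]]$p_adjusted)
  res_adj <- search_combinations(sessions[1:2], montage = montage,
                                 min_size = 5, n_components = 3, adjust = TRUE)
  expect_true(is.numeric(res_adj[[1]]$p_adjusted))
})

test_that("the best candidate per subject is the planted subset on strong data", {
  wins <- 0L
  for (seed in 1:12) {
    ep <- quick_session(seed = 40 + seed, n_ch = 6, n_trials = 30, effect = 8)
    true_sub <- c("FC3", "C3", "C4", "CP3")  # contains both planted channels
    rand_sub <- c("FC3", "FC4", "Cz", "CP3") # contains neither
    pick <- best_per_subject(list(rand_sub, true_sub), ep, n_components = 4)
    if (identical(as.character(pick$subset),
                  intersect(ep$ch_names, true_sub))) wins <- wins + 1L
  }
  expect_gte(wins, 11L)

  # single candidate returns itself; duplicates collapse to the same winner
  ep <- quick_session(seed = 60, n_ch = 4, n_trials = 15)
  one <- best_per_subject(list(c("C3", "C4")), ep, n_components = 2)
  expect_identical(as.character(one$subset), c("C3", "C4"))
  dup <- best_per_subject(list(c("C3", "C4"), c("c3", "C4"), c("C3", "C4")),
                          ep, n_components = 2)
  expect_identical(dup$subset, one$subset)
  expect_identical(dup$result, one$result)
  expect_error(best_per_subject(list(), ep), class = "cspselect_validation_error")
})
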