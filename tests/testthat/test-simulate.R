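test_that("generation is a pure function of the config", {
  cfg <- sim_config(n_channels = 4, n_trials_per_class = 5, n_samples = 64,
                    disc_channels = c("C3", "C4"), seed = 11)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  # balanced labels and declared dimensions
  expect_equal(unname(table(a$labels)), c(5L, 5L), ignore_attr = TRUE)
  expect_identical(dim(a$data), c(10L, 4L, 64L))
  # subject sessions: distinct data, shared montage, reproducible pair
  subj1 <- generate_subject(cfg, 2)
  subj2 <- generate_subject(cfg, 2)
  expect_false(identical(subj1[[1]]$data, subj1[[2]]$data))
  expect_identical(subj1[[1]]$ch_names, subj1[[2]]$ch_names)
  expect_identical(subj1[[1]]$data, subj2[[1]]$data)
  expect_identical(subj1[[2]]$data, subj2[[2]]$data)
  expect_false(identical(subj1[[1]]$session_id, subj1[[2]]$session_id))
  expect_error(generate_subject(cfg, 0), class = "cspselect_validation_error")
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(effect = 0.5), class = "cspselect_validation_error")
  expect_error(sim_config(mixing_strength = 1), class = "cspselect_validation_error")
  expect_error(sim_config(disc_channels = "XX9"), class = "cspselect_validation_error")
  expect_error(sim_config(n_trials_per_class = 0), class = "cspselect_validation_error")
  expect_error(sim_config(band = c(8, 70), sfreq = 128),
               class = "cspselect_validation_error")
})

test_that("effect controls the class variance ratio on boosted channels", {
  # sample-variance oracle: left boosts C3, right boosts C4
  cfg <- sim_config(n_channels = 4, ch_names = c("C3", "Cz", "C4", "CP3"),
                    disc_channels = c("C3", "C4"), effect = 4,
                    mixing_strength = 0, n_trials_per_class = 60,
                    n_samples = 256, seed = 3)
  ep <- generate_session(cfg)
  ratio <- function(ch) {
    i <- match(ch, ep$ch_names)
    mean(apply(ep$data[ep$labels == "left", i, ], 1, var)) /
      mean(apply(ep$data[ep$labels == "right", i, ], 1, var))
  }
  expect_gt(ratio("C3"), 3.0)
  expect_lt(ratio("C3"), 5.0)
  expect_gt(1 / ratio("C4"), 3.0)
  expect_lt(1 / ratio("C4"), 5.0)
  # contrast localization: a non-discriminative channel is class-neutral
  expect_gt(ratio("Cz"), 0.8)
  expect_lt(ratio("Cz"), 1.25)
})

test_that("effect = 1 makes the two classes exchangeable", {
  # per-trial log-variances of a nominally discriminative channel compared
  # between classes; the two-sample test should reject at the 1% level only
  # at its nominal rate
  rejections <- 0L
  for (seed in 1:100) {
    ep <- generate_session(sim_config(n_channels = 4, n_trials_per_class = 20,
                                      n_samples = 64, effect = 1,
                                      disc_channels = c("C3", "C4"),
                                      mixing_strength = 0, seed = seed))
    i <- match("C3", ep$ch_names)
    lv <- log(apply(ep$data[, i, ], 1, var))
    p <- t.test(lv[ep$labels == "left"], lv[ep$labels == "right"])$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 5L)
})

test_that("generated sessions are detectable by CSP", {
  hits <- 0L
  for (seed in 1:25) {
    ep <- quick_session(seed = seed, n_ch = 6, n_trials = 40, effect = 4)
    top <- fit_csp(class_covariances(ep), n_components = 1)$eigvals[1]
    if (max(top, 1 - top) > 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 23L)
})

test_that("spatial mixing leaks contrast into neighbouring channels", {
  cfg <- sim_config(n_channels = 4, ch_names = c("C3", "Cz", "C4", "CP3"),
                    disc_channels = c("C3", "C4"), effect = 8,
                    mixing_strength = 0.4, n_trials_per_class = 40,
                    n_samples = 128, seed = 9)
  ep <- generate_session(cfg)
  i <- match("CP3", ep$ch_names)  # neighbour of right-boosted C4 only
  vL <- mean(apply(ep$data[ep$labels == "left", i, ], 1, var))
  vR <- mean(apply(ep$data[ep$labels == "right", i, ], 1, var))
  expect_gt(vR / vL, 1.2)
})
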