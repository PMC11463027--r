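test_that("conjugate updates pool dichotomic trial counts", {
  prior <- beta_prior(6, 4)
  one <- posterior_from_results(fake_result(10, 15), prior)
  expect_equal(one$alpha, 16)
  expect_equal(one$beta, 9)
  # additivity: two subjects pool like one concatenated result
  two <- posterior_from_results(list(fake_result(10, 15), fake_result(5, 5)),
                                prior)
  expect_equal(two$alpha, 21)
  expect_equal(two$beta, 9)
  expect_equal(unclass(two)[c("alpha", "beta")],
               unclass(posterior_from_results(fake_result(15, 20),
                                              prior))[c("alpha", "beta")])
  # sequential updates equal the concatenated update
  mid <- posterior_from_results(fake_result(10, 15), prior)
  seqd <- posterior_from_results(fake_result(5, 5),
                                 beta_prior(mid$alpha, mid$beta))
  expect_equal(seqd$alpha, two$alpha)
  expect_equal(seqd$beta, two$beta)
  expect_error(posterior_from_results(list(), prior),
               class = "cspselect_validation_error")
  expect_error(beta_prior(0, 1), class = "cspselect_validation_error")
})

test_that("Monte-Carlo ratios match the closed-form mean and concentrate", {
  post <- structure(list(alpha = 16, beta = 9), class = "beta_posterior")
  s <- mc_improvement(post, post, n_draws = 10000, seed = 5)
  # E[a] * E[1/b] = (16/25) * (24/15) = 1.024 for independent identical draws
  expect_lt(abs(s$mean_fraction - 1.024), 3 * s$mc_se)
  expect_equal(s$pct_improvement, 100 * (s$mean_fraction - 1))
  # concentration: tight posteriors give a ratio pinned near 1
  tight <- structure(list(alpha = 1000, beta = 1), class = "beta_posterior")
  s2 <- mc_improvement(tight, tight, n_draws = 10000, seed = 6)
  expect_gt(s2$mean_fraction, 0.99)
  expect_lt(s2$mean_fraction, 1.01)
  # bit-identical reruns under a fixed seed
  expect_identical(mc_improvement(post, post, n_draws = 500, seed = 9),
                   mc_improvement(post, post, n_draws = 500, seed = 9))
  # diverging reciprocal mean is signalled
  flat <- structure(list(alpha = 1, beta = 1), class = "beta_posterior")
  expect_warning(mc_improvement(post, flat, n_draws = 10, seed = 1),
                 class = "cspselect_divergence_warning")
})

test_that("Monte-Carlo standard error shrinks as 1/sqrt(n)", {
  post <- structure(list(alpha = 160, beta = 90), class = "beta_posterior")
  s_small <- mc_improvement(post, post, n_draws = 100, seed = 3)
  s_big <- mc_improvement(post, post, n_draws = 10000, seed = 3)
  expect_gt(s_small$mc_se / s_big$mc_se, 5)
  expect_lt(s_small$mc_se / s_big$mc_se, 20)
})

test_that("the prior washes out at large pooled trial counts", {
  informative <- posterior_from_results(fake_result(7000, 10000), beta_prior(6, 4))
  flat <- posterior_from_results(fake_result(7000, 10000), beta_prior(1, 1))
  mean_of <- function(p) p$alpha / (p$alpha + p$beta)
  expect_lt(abs(mean_of(informative) - mean_of(flat)), 1e-3)
})

test_that("variant evaluation is order-invariant and Comb dominates", {
  subj_results <- function(corrects, total = 50) lapply(corrects, fake_result,
                                                        total = total)
  baseline <- subj_results(c(30, 32, 28))
  variants <- list(B16 = subj_results(c(31, 30, 29)),
                   Algo = subj_results(c(35, 28, 33)),
                   PSA1 = subj_results(c(33, 36, 27)))
  s1 <- evaluate_variants(variants, baseline, n_draws = 2000, seed = 11,
                          comb_from = c("Algo", "PSA1"))
  s2 <- evaluate_variants(variants[c(3, 1, 2)], baseline, n_draws = 2000,
                          seed = 11, comb_from = c("Algo", "PSA1"))
  for (nm in names(s1)) expect_identical(s1[[nm]], s2[[nm]])
  # Comb pools the per-subject best: successes dominate each constituent
  posts <- attr(s1, "posteriors")
  expect_gte(posts$Comb$successes, posts$Algo$successes)
  expect_gte(posts$Comb$successes, posts$PSA1$successes)
  expect_equal(posts$Comb$successes, 35 + 36 + 33)
  # coverage mismatch is rejected
  expect_error(evaluate_variants(list(B16 = baseline[1:2]), baseline,
                                 n_draws = 10),
               class = "cspselect_validation_error")
  expect_error(evaluate_variants(variants, baseline, comb_from = "nope",
                                 n_draws = 10),
               class = "cspselect_validation_error")
})

test_that("posterior densities are exact beta densities that integrate to one", {
  grid <- seq(1e-6, 1 - 1e-6, length.out = 4001)
  uniform <- structure(list(alpha = 1, beta = 1), class = "beta_posterior")
  ramp <- structure(list(alpha = 2, beta = 1), class = "beta_posterior")
  tab <- posterior_density_table(list(u = uniform, r = ramp), grid)
  expect_true(all(tab$density[tab$posterior == "u"] == 1))
  expect_equal(posterior_density_table(list(r = ramp), 0.5)$density, 1)
  # trapezoid quadrature oracle
  dens <- tab$density[tab$posterior == "r"]
  area <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  expect_equal(area, 1, tolerance = 1e-3)
  expect_error(posterior_density_table(list(uniform), c(0, 0.5)),
               class = "cspselect_domain_error")
})
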