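test_that("class covariances converge to the scaled identity for white noise", {
  # law-of-large-numbers oracle: i.i.d. unit-variance noise in both classes
  set.seed(2)
  n_ch <- 4; n_samples <- 25000
  ep <- eeg_epochs(array(rnorm(4 * n_ch * n_samples), c(4, n_ch, n_samples)),
                   c("left", "right", "left", "right"),
                   montage_16()[1:n_ch], 128)
  cc <- class_covariances(ep)
  expect_lt(max(abs(cc$sigma1 - diag(n_ch) / n_ch)), 0.02)
  expect_lt(max(abs(cc$sigma2 - diag(n_ch) / n_ch)), 0.02)
  # structural invariants
  expect_lt(max(abs(cc$sigma1 - t(cc$sigma1))), 1e-12)
  expect_equal(sum(diag(cc$sigma1)), 1, tolerance = 1e-9)
  expect_equal(sum(diag(cc$sigma2)), 1, tolerance = 1e-9)
  expect_gte(min(eigen(cc$sigma1, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  # full shrinkage forces the target exactly
  cc1 <- class_covariances(ep, shrinkage = 1)
  expect_equal(cc1$sigma1, diag(n_ch) / n_ch, tolerance = 1e-12)
  expect_equal(cc1$sigma2, diag(n_ch) / n_ch, tolerance = 1e-12)
})

test_that("perfectly correlated channels give a rank-1 covariance", {
  set.seed(3)
  base <- matrix(rnorm(2 * 64), 2, 64, byrow = TRUE)
  x <- array(0, c(2, 2, 64))
  x[1, 1, ] <- base[1, ]; x[1, 2, ] <- base[1, ]
  x[2, 1, ] <- base[2, ]; x[2, 2, ] <- base[2, ]
  # duplicate trials so each class has two
  x <- x[c(1, 1, 2, 2), , ]
  ep <- eeg_epochs(x, c("left", "left", "right", "right"), c("C3", "C4"), 128)
  cc <- class_covariances(ep)
  expect_lt(abs(cc$sigma1[1, 2] - cc$sigma1[1, 1]), 1e-12)
  ev <- eigen(cc$sigma1, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2], 1e-12)
  # a class with < 2 trials is rejected
  expect_error(class_covariances(
    eeg_epochs(x[1:3, , ], c("left", "left", "right"), c("C3", "C4"), 128)),
    class = "cspselect_validation_error")
})

test_that("CSP recovers closed-form eigenstructure", {
  # identical covariances: perfect symmetry, all eigenvalues 1/2
  s <- random_spd(4)
  m_eq <- fit_csp(class_covs(s, s), 4)
  expect_equal(m_eq$eigvals, rep(0.5, 4), tolerance = 1e-9)

  # diagonal pair summing to the identity: lambda = {0.9, 0.1}, axis filters
  m <- fit_csp(class_covs(diag(c(0.9, 0.1)), diag(c(0.1, 0.9))), 2)
  expect_equal(m$eigvals, c(0.9, 0.1), tolerance = 1e-10)
  w <- abs(m$filters / sqrt(rowSums(m$filters^2)))
  expect_equal(unname(w), diag(2), tolerance = 1e-6)
})

test_that("the leading filter maximizes the Rayleigh ratio", {
  set.seed(7)
  for (rep in 1:5) {
    cc <- class_covs(random_spd(6), random_spd(6))
    m <- fit_csp(cc, 6)
    ray <- function(v) c(v %*% cc$sigma1 %*% v) /
      c(v %*% (cc$sigma1 + cc$sigma2) %*% v)
    lead <- m$filters[which.max(m$eigvals), ]
    rand <- replicate(1000, ray(rnorm(6)))
    expect_gte(ray(lead) + 1e-12, max(rand))
  }
})

test_that("filters simultaneously diagonalize both class covariances", {
  set.seed(8)
  cc <- class_covs(random_spd(5), random_spd(5))
  m <- fit_csp(cc, 5)
  d1 <- m$filters %*% cc$sigma1 %*% t(m$filters)
  d2 <- m$filters %*% cc$sigma2 %*% t(m$filters)
  expect_lt(max(abs(d1 - diag(diag(d1)))), 1e-8)
  expect_lt(max(abs(d2 - diag(diag(d2)))), 1e-8)
  expect_equal(unname(diag(d1) + diag(d2)), rep(1, 5), tolerance = 1e-8)
  expect_equal(unname(diag(d1)), m$eigvals, tolerance = 1e-8)

  # swapping class roles maps lambda to 1 - lambda
  m_swap <- fit_csp(class_covs(cc$sigma2, cc$sigma1), 5)
  expect_equal(sort(m_swap$eigvals), sort(1 - m$eigvals), tolerance = 1e-8)

  # patterns are the mixing counterpart: filters %*% t(patterns) = identity
  expect_equal(unname(m$filters %*% t(m$patterns)), diag(5), tolerance = 1e-8)
})

test_that("fits are deterministic and scale-invariant", {
  ep <- quick_session(seed = 4)
  m1 <- fit_csp(class_covariances(ep), 4)
  m2 <- fit_csp(class_covariances(ep), 4)
  expect_identical(m1, m2)
  scaled <- ep; scaled$data <- ep$data * 7.3
  m3 <- fit_csp(class_covariances(scaled), 4)
  expect_equal(m3$eigvals, m1$eigvals, tolerance = 1e-10)
  # sign convention: largest-|coefficient| of every filter is positive
  expect_true(all(apply(m1$filters, 1, function(w) w[which.max(abs(w))] > 0)))
})

test_that("log-variance features match direct projection", {
  ep <- quick_session(seed = 5, n_ch = 4, n_trials = 10)
  m <- fit_csp(class_covariances(ep), 3)
  feats <- apply_csp(m, ep)
  # projection oracle on a handful of trials
  for (tr in c(1, 5, 12)) {
    for (j in 1:3) {
      proj <- drop(m$filters[j, ] %*% ep$data[tr, , ])
      expect_equal(unname(feats[tr, j]), log(var(proj)), tolerance = 1e-10)
    }
  }
  # identical trials give identical features
  dup <- ep; dup$data[2, , ] <- dup$data[1, , ]
  fd <- apply_csp(m, dup)
  expect_identical(fd[1, ], fd[2, ])
  # scaling a trial by c adds 2 log|c| to every feature
  sc <- ep; sc$data[3, , ] <- sc$data[3, , ] * 4
  fs <- apply_csp(m, sc)
  expect_equal(fs[3, ], feats[3, ] + 2 * log(4), tolerance = 1e-10)
  # channel mismatch is a validation error naming the difference
  expect_error(apply_csp(m, subset_channels(ep, ep$ch_names[1:3])),
               class = "cspselect_validation_error")
})

test_that("degenerate composite covariance advises shrinkage", {
  z <- matrix(0, 3, 3); z[1, 1] <- 1
  expect_error(fit_csp(class_covs(z, z), 2), "shrinkage",
               class = "cspselect_numerical_error")
  expect_error(fit_csp(class_covs(diag(3), diag(3)), 4),
               class = "cspselect_validation_error")
})
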