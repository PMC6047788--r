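test_that("monotone sequences concentrate on the extreme patterns", {
  up <- ordinal_distribution(1:50, D = 3)
  expect_equal(up$probabilities[1], 1)       # identity is lexicographically first
  expect_identical(permutation_entropy(up), 0)
  down <- ordinal_distribution(50:1, D = 3)
  expect_equal(down$probabilities[6], 1)     # reversal is lexicographically last
  expect_identical(permutation_entropy(down), 0)
  expect_equal(sum(up$probabilities), 1, tolerance = 1e-12)
  expect_length(up$probabilities, 6)
})

test_that("iid noise patterns are exchangeable and near-maximal entropy", {
  set.seed(42)
  d <- ordinal_distribution(runif(100000), D = 3)
  expect_true(all(abs(d$probabilities - 1 / 6) < 0.01))
  set.seed(43)
  d4 <- ordinal_distribution(rnorm(17520), D = 4)
  expect_gte(permutation_entropy(d4), 0.99)
})

test_that("entropy endpoints and monotone-transform invariance hold", {
  uniform <- dist_with_probs(rep(1 / 24, 24), D = 4)
  expect_equal(permutation_entropy(uniform), 1)
  expect_equal(statistical_complexity(uniform), 0)
  expect_equal(ordinal_fisher(uniform), 0)

  set.seed(8)
  x <- cumsum(rnorm(3000))
  a <- ordinal_distribution(x, D = 4)
  b <- ordinal_distribution(exp(x / 5), D = 4)      # strictly monotone map
  expect_equal(a$probabilities, b$probabilities)
})

test_that("complexity vanishes at order and randomness, peaks between", {
  expect_equal(statistical_complexity(ordinal_distribution(1:100, D = 4)), 0)
  pink <- info_measures(colored_noise(noise_spec(beta = 1, n = 8192, seed = 1)))
  white <- info_measures(colored_noise(noise_spec(beta = 0, n = 8192, seed = 1)))
  expect_gt(pink$C, white$C)
  # C <= H-dependent bound, C in [0, 1)
  set.seed(9)
  for (i in 1:20) {
    p <- stats::rgamma(24, 1); p <- p / sum(p)
    d <- dist_with_probs(p, D = 4)
    expect_gte(statistical_complexity(d), 0)
    expect_lt(statistical_complexity(d), 1)
  }
})

test_that("ordinal Fisher is normalized and reversal-symmetric", {
  extreme_first <- dist_with_probs(c(1, rep(0, 23)), D = 4)
  extreme_last <- dist_with_probs(c(rep(0, 23), 1), D = 4)
  expect_equal(ordinal_fisher(extreme_first), 1)
  expect_equal(ordinal_fisher(extreme_last), 1)
  interior <- dist_with_probs(c(rep(0, 11), 1, rep(0, 12)), D = 4)
  expect_equal(ordinal_fisher(interior), 1)
  set.seed(10)
  for (i in 1:20) {
    p <- stats::rgamma(24, 0.5); p <- p / sum(p)
    d <- dist_with_probs(p, D = 4)
    f <- ordinal_fisher(d)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_equal(f, ordinal_fisher(dist_with_probs(rev(p), D = 4)))
  }
})

test_that("embedding preconditions are enforced", {
  expect_error(ordinal_distribution(1:4, D = 4), class = "critisus_validation_error")
  expect_error(ordinal_distribution(rep(2, 100), D = 3),
               class = "critisus_validation_error")
  expect_error(ordinal_distribution(rnorm(100), D = 1),
               class = "critisus_validation_error")
  d <- ordinal_distribution(c(1, 1, 2, 1, 3, 2, 2, 4, 1, 5, 2), D = 3)
  expect_gt(d$tie_count, 0)                      # ties logged, not fatal
  expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
})

test_that("entropy decreases with spectral exponent across the noise family", {
  grid <- c(0, 0.5, 1, 1.5, 2, 2.5)
  mean_H <- vapply(grid, function(b) {
    mean(vapply(1:5, function(s) {
      info_measures(colored_noise(noise_spec(beta = b, n = 4096,
                                             seed = 50 * s + round(2 * b))))$H
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_H) < 0))
})

test_that("quadratic complexity-entropy fit recovers exact coefficients", {
  H <- seq(0.1, 0.9, length.out = 9)
  exact <- tibble::tibble(H = H, C = 2 * H * (1 - H))
  fit <- fit_entropy_complexity(exact)
  expect_equal(fit$a, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  flat <- fit_entropy_complexity(tibble::tibble(H = H, C = 0))
  expect_equal(flat$a, 0)

  expect_error(fit_entropy_complexity(tibble::tibble(H = rep(0.5, 6), C = H[1:6])),
               class = "critisus_validation_error")
  expect_error(fit_entropy_complexity(tibble::tibble(H = 1:3 / 4, C = 1:3 / 4)),
               class = "critisus_validation_error")
})
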