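test_that("periodogram locates tones and satisfies Parseval", {
  day <- (0:4799) / 48
  ps <- periodogram(sin(2 * pi * 2 * day))
  expect_equal(ps$frequency[which.max(ps$power)], 2)
  expect_true(all(diff(ps$frequency) > 0))
  expect_true(all(ps$power >= 0))

  x <- rnorm(4096)
  ps2 <- periodogram(x)
  expect_equal(sum(ps2$power) * 48 / 4096, mean((x - mean(x))^2),
               tolerance = 0.01)

  expect_true(all(periodogram(rep(0, 128) + c(1e-30, rep(0, 127)))$power >= 0))
  expect_error(periodogram(rnorm(32)), class = "critisus_validation_error")
})

test_that("single power-law fit is exact on noiseless spectra", {
  f <- year_freqs(4096)
  for (b in c(1, 2)) {
    fit <- fit_single_power_law(make_ps(f, f^-b))
    expect_equal(fit$beta, b, tolerance = 1e-10)
    expect_lt(fit$rss, 1e-20)
    expect_equal(fit$k, 3L)
  }
  # scale equivariance: amplitude moves, exponent does not
  f1 <- fit_single_power_law(make_ps(f, f^-1))
  f2 <- fit_single_power_law(make_ps(f, 100 * f^-1))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f2$log_amplitude - f1$log_amplitude, 2, tolerance = 1e-10)
})

test_that("single fit recovers generator exponents and drops bad points", {
  betas <- vapply(1:20, function(s) {
    fit_single_power_law(
      periodogram(colored_noise(noise_spec(beta = 1, n = 4096, seed = s)))
    )$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 1), 0.15)

  f <- year_freqs(128)
  p <- f^-1
  p[3] <- 0
  expect_warning(fit <- fit_single_power_law(make_ps(f, p)),
                 "excluded")
  expect_equal(fit$n_points, length(f) - 1L)
  expect_error(suppressWarnings(fit_single_power_law(make_ps(f[1:12], c(f[1:9]^-1, 0, 0, 0)))),
               class = "critisus_validation_error")
})

test_that("double power-law fit recovers broken spectra and nests the single fit", {
  f <- year_freqs(8192)
  # continuous broken law: beta 0.5 below 1 cpd, 2 above
  broken <- make_ps(f, ifelse(f < 1, f^-0.5, f^-2))
  d <- fit_double_power_law(broken)
  expect_equal(d$beta1, 0.5, tolerance = 0.1)
  expect_equal(d$beta2, 2, tolerance = 0.1)
  expect_lt(abs(d$crossover_frequency - 1) / 1, 0.2)
  expect_equal(d$k, 5L)
  s <- fit_single_power_law(broken)
  expect_lte(d$rss, s$rss)
  expect_lt(compare_models(s, d)$dbic, 0)

  # degenerate single-law input: both slopes collapse to the single exponent
  pure <- make_ps(f, f^-1)
  d1 <- fit_double_power_law(pure)
  s1 <- fit_single_power_law(pure)
  expect_equal(d1$beta1, 1, tolerance = 0.05)
  expect_equal(d1$beta2, 1, tolerance = 0.05)
  expect_lte(d1$rss, s1$rss + 1e-12)
  expect_true(d1$crossover_frequency > min(f) && d1$crossover_frequency < max(f))
})

test_that("BIC follows n log(rss/n) + k log(n)", {
  n <- 8760
  expect_equal(bic_from_rss(n, n, 3), 3 * log(n))
  expect_equal(bic_from_rss(100, n, 3) - bic_from_rss(100, n, 5), -2 * log(n))
  expect_equal(bic_from_rss(200, n, 3) - bic_from_rss(100, n, 3), n * log(2))
  exact <- bic_from_rss(0, 100, 3)
  expect_identical(as.numeric(exact), -Inf)
  expect_true(attr(exact, "exact_fit"))
  expect_error(bic_from_rss(10, 3, 3), class = "critisus_validation_error")
  expect_error(bic_from_rss(-1, 100, 3), class = "critisus_validation_error")
})

test_that("model comparison prefers the simpler law at equal fit quality", {
  f <- year_freqs(4096)
  s <- fit_single_power_law(make_ps(f, exp(rnorm(length(f), -log(f), 0.5))))
  fake_double <- structure(
    list(beta1 = s$beta, beta2 = s$beta, crossover_frequency = 1,
         log_amplitude = s$log_amplitude, rss = s$rss,
         n_points = s$n_points, k = 5L,
         bic = bic_from_rss(s$rss, s$n_points, 5L)),
    class = "double_powerlaw_fit"
  )
  cmp <- compare_models(s, fake_double)
  expect_equal(cmp$dbic, 2 * log(s$n_points))
  expect_identical(cmp$preferred, "single")

  mismatched <- fake_double
  mismatched$n_points <- 10L
  expect_error(compare_models(s, mismatched),
               class = "critisus_validation_error")
})

test_that("noise classes split at beta = 0.5 and 1.5", {
  expect_identical(classify_noise(0.3), "white")
  expect_identical(classify_noise(0.5), "white")
  expect_identical(classify_noise(1.0), "pink")
  expect_identical(classify_noise(1.8), "brown")
  expect_identical(classify_noise(1.5), "brown")
  expect_error(classify_noise(NaN), class = "critisus_validation_error")
})
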