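test_that("linear detrending is exact on ramps and orthogonal to the line", {
  t_idx <- 0:499
  det <- detrend_linear(3 + 0.02 * t_idx)
  expect_equal(det$residuals, rep(0, 500), tolerance = 1e-10)
  expect_equal(det$slope, 0.02)
  expect_equal(det$intercept, 3)

  # ramp + sinusoid: compare against the closed-form OLS line
  y <- 1 + 0.005 * t_idx + sin(2 * pi * t_idx / 48)
  slope_oracle <- sum((t_idx - mean(t_idx)) * (y - mean(y))) /
    sum((t_idx - mean(t_idx))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(t_idx)
  det2 <- detrend_linear(y)
  expect_equal(det2$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(det2$residuals, y - intercept_oracle - slope_oracle * t_idx,
               tolerance = 1e-8)
  expect_lt(abs(sum(det2$residuals)), 1e-8)
  expect_lt(abs(sum(det2$residuals * t_idx)), 1e-5)

  # trendless zero-mean noise passes through essentially unchanged
  set.seed(4)
  z <- rnorm(2000)
  det3 <- detrend_linear(z)
  expect_lt(abs(det3$slope), 3 / sqrt(sum((0:1999 - 999.5)^2)))
  expect_gt(cor(det3$residuals, z), 0.999)

  expect_error(detrend_linear(c(1, NA, 3, 4)),
               class = "critisus_precondition_error")
})

test_that("notch filter removes its target tone but not broadband power", {
  day <- (0:17519) / 48
  tone <- sin(2 * pi * day)
  out <- notch_filter(tone, notch_setting(1, 12))
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(tone^2)), 0.10)

  set.seed(7)
  wn <- rnorm(17520)
  filtered <- wn
  for (ns in default_notches()) filtered <- notch_filter(filtered, ns)
  expect_gt(var(filtered) / var(wn), 0.95)

  expect_identical(notch_filter(rep(0, 500), notch_setting(1, 12)),
                   rep(0, 500))
  expect_error(notch_filter(tone, notch_setting(24, 12)),
               class = "critisus_validation_error")
  expect_error(notch_setting(1, -2), class = "critisus_validation_error")
})

test_that("notch cascade is stable and harmonic order is interchangeable", {
  impulse <- rep(0, 4800); impulse[2400] <- 1
  for (ns in default_notches()) {
    resp <- notch_filter(impulse, ns)
    expect_false(any(!is.finite(resp)))
    # zero-phase response decays away from the impulse
    expect_lt(max(abs(resp[c(1:100, 4701:4800)])), 1e-6)
  }
  x <- colored_noise(noise_spec(beta = 1, n = 8192, seed = 3))
  a <- notch_filter(notch_filter(x, notch_setting(2, 30)), notch_setting(3, 30))
  b <- notch_filter(notch_filter(x, notch_setting(3, 30)), notch_setting(2, 30))
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 1e-8)
})

test_that("fluctuation extraction attenuates diurnal lines to background", {
  raw <- make_site_year(
    noise_spec(beta = 1, n = 17520, sigma = 1, seed = 21),
    contamination_spec(diurnal_amplitude = 10, harmonic_amplitudes = c(3, 1),
                       trend_slope = 1e-4)
  )
  fl <- make_fluctuations(raw)
  expect_equal(nrow(fl), 17520)
  expect_lt(abs(mean(fl$value)), 1e-6 * sd(fl$value))
  ps <- periodogram(fl)
  for (f0 in c(1, 2, 3)) {
    centre <- mean(ps$power[abs(ps$frequency - f0) < 0.01])
    background <- stats::median(
      ps$power[abs(ps$frequency - f0) > 0.1 & abs(ps$frequency - f0) < 0.5]
    )
    expect_lt(10 * log10(centre / background), 3)  # no residual peak
  }
  prov <- attr(fl, "provenance")
  expect_equal(length(prov$notches), 3)
  expect_equal(prov$trend_slope, 1e-4, tolerance = 0.05)
})

test_that("pure colored noise survives preprocessing nearly unchanged", {
  # detrending removes a seed-dependent slice of low-frequency power, so the
  # passthrough correlation is assessed on an ensemble median
  cors <- vapply(1:8, function(s) {
    x <- colored_noise(noise_spec(beta = 1, n = 17520, seed = 30 + s))
    cor(make_fluctuations(x)$value, x)
  }, numeric(1))
  expect_gt(stats::median(cors), 0.95)

  x <- colored_noise(noise_spec(beta = 1, n = 17520, seed = 31))
  beta_hat <- fit_single_power_law(periodogram(make_fluctuations(x)))$beta
  expect_lt(abs(beta_hat - 1), 0.2)

  zero <- make_fluctuations(rep(0, 1000) + seq(0, 1, length.out = 1000))
  expect_equal(zero$value, rep(0, 1000), tolerance = 1e-10)

  gappy <- make_site_year(noise_spec(n = 960, seed = 1),
                          contamination_spec(gap_blocks = list(c(10, 3))))
  expect_error(make_fluctuations(gappy), class = "critisus_precondition_error")
})
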