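#' Periodogram of a fluctuation series
#'
#' Standard FFT periodogram at the positive Fourier frequencies, scaled as a
#' one-sided power spectral density in cycles/day so that
#' \eqn{\sum S(f_k)\,\Delta f} equals the series variance (Parseval).
#' The zero frequency is excluded.
#'
#' @param fluct A `fluctuation_series` (or numeric vector).
#' @param samples_per_day Sampling rate; taken from `fluct` when available.
#' @return Tibble of class `power_spectrum` with columns `frequency`
#'   (cycles/day, ascending) and `power`, and attribute `n_series`.
#' @export
periodogram <- function(fluct, samples_per_day = NULL) {
  if (is.data.frame(fluct)) {
    samples_per_day <- samples_per_day %||%
      attr(fluct, "samples_per_day") %||% HALF_HOURLY
    x <- fluct$value
  } else {
    samples_per_day <- samples_per_day %||% HALF_HOURLY
    x <- as.numeric(fluct)
  }
  n <- length(x)
  if (n < 64) {
    stop_critisus("Series too short for spectral analysis (need >= 64).",
                  "critisus_validation_error")
  }
  x <- x - mean(x)
  X <- fft(x)
  nf <- n %/% 2
  fs <- samples_per_day
  freq <- seq_len(nf) * fs / n
  # one-sided density: doubled except at Nyquist (even n)
  p <- Mod(X[2:(nf + 1L)])^2 / (n * fs)
  doubling <- rep(2, nf)
  if (n %% 2L == 0L) doubling[nf] <- 1
  structure(
    tibble(frequency = freq, power = doubling * p),
    n_series = n, samples_per_day = fs,
    class = c("power_spectrum", class(tibble(frequency = freq)))
  )
}

#' Bayesian Information Criterion from a residual sum of squares
#'
#' `n * log(rss / n) + k * log(n)`, the Gaussian-likelihood BIC with the
#' error variance counted among the `k` parameters (k = 3 for the single
#' power law, k = 5 for the double). Lower is better.
#'
#' @param rss Residual sum of squares (log10 spectrum space).
#' @param n_points Number of fitted spectrum points.
#' @param k Parameter count.
#' @return BIC value; `-Inf` with attribute `exact_fit = TRUE` when `rss == 0`.
#' @export
bic_from_rss <- function(rss, n_points, k) {
  assert_scalar_number(rss, "rss")
  assert_scalar_number(n_points, "n_points")
  assert_scalar_number(k, "k")
  if (rss < 0) stop_critisus("`rss` must be >= 0.", "critisus_validation_error")
  if (n_points <= k) {
    stop_critisus("`n_points` must exceed `k`.", "critisus_validation_error")
  }
  if (rss == 0) {
    return(structure(-Inf, exact_fit = TRUE))
  }
  n_points * log(rss / n_points) + k * log(n_points)
}

log_log_points <- function(spectrum) {
  keep <- spectrum$power > 0 & is.finite(spectrum$power)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(sprintf("%d nonpositive/nonfinite power values excluded from log-log fit.",
                 n_dropped))
  }
  list(u = log10(spectrum$frequency[keep]), y = log10(spectrum$power[keep]),
       n_dropped = n_dropped)
}

#' Fit a single power law to a power spectrum
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)`; the
#' spectral exponent `beta` is the negative slope. Nonpositive power values
#' are excluded with a warning.
#'
#' @param spectrum A `power_spectrum`.
#' @return Object of class `powerlaw_fit`: `beta`, `log_amplitude`, `rss`
#'   (log10 space), `n_points`, `k = 3`, `bic`.
#' @export
fit_single_power_law <- function(spectrum) {
  pts <- log_log_points(spectrum)
  if (length(pts$u) < 10) {
    stop_critisus("Fewer than 10 positive-power points; cannot fit.",
                  "critisus_validation_error")
  }
  fit <- lm.fit(cbind(1, pts$u), pts$y)
  rss <- sum(fit$residuals^2)
  n <- length(pts$u)
  structure(
    list(beta = -unname(fit$coefficients[2]),
         log_amplitude = unname(fit$coefficients[1]),
         rss = rss, n_points = n, k = 3L,
         bic = bic_from_rss(rss, n, 3L),
         n_dropped = pts$n_dropped),
    class = "powerlaw_fit"
  )
}

# Hinge (broken-line) OLS at a fixed crossover in log10-frequency space.
hinge_rss <- function(u, y, uc) {
  h <- pmax(0, u - uc)
  fit <- lm.fit(cbind(1, u, h), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(rss = sum(fit$residuals^2),
       log_amplitude = unname(cf[1]),
       beta1 = -unname(cf[2]),
       beta2 = -(unname(cf[2]) + unname(cf[3])))
}

#' Fit a broken (double) power law to a power spectrum
#'
#' Continuous piecewise-linear model in log-log space: slope `-beta1` below
#' the crossover frequency, `-beta2` above, continuous at the crossover.
#' Fitted by profiling the crossover (the model is linear given the
#' crossover) over 20 log-spaced candidates between the 5th and 95th
#' percentile frequencies, refining locally, then polishing all four
#' parameters by Nelder-Mead. The hinge regression nests the single power
#' law (`beta1 == beta2`), so the double-fit RSS never exceeds the
#' single-fit RSS on the same spectrum.
#'
#' @param spectrum A `power_spectrum`.
#' @param n_starts Number of crossover candidates in the coarse grid.
#' @return Object of class `double_powerlaw_fit`: `beta1`, `beta2`,
#'   `crossover_frequency` (cycles/day), `log_amplitude`, `rss`, `n_points`,
#'   `k = 5`, `bic`.
#' @export
fit_double_power_law <- function(spectrum, n_starts = 20L) {
  pts <- suppressWarnings(log_log_points(spectrum))
  u <- pts$u; y <- pts$y
  if (length(u) < 20) {
    stop_critisus("Fewer than 20 points; cannot fit a broken power law.",
                  "critisus_validation_error")
  }
  f_lo <- quantile(10^u, 0.05, names = FALSE)
  f_hi <- quantile(10^u, 0.95, names = FALSE)
  grid <- log10(exp(seq(log(f_lo), log(f_hi), length.out = n_starts)))

  cand <- lapply(grid, function(uc) c(uc = uc, rss = hinge_rss(u, y, uc)$rss))
  rss_grid <- vapply(cand, `[[`, numeric(1), "rss")
  best_i <- which.min(rss_grid)

  # local refinement between the neighbours of the best coarse candidate
  lo <- grid[max(1L, best_i - 1L)]
  hi <- grid[min(length(grid), best_i + 1L)]
  fine <- seq(lo, hi, length.out = 25L)
  rss_fine <- vapply(fine, function(uc) hinge_rss(u, y, uc)$rss, numeric(1))
  uc_best <- fine[which.min(rss_fine)]
  best <- hinge_rss(u, y, uc_best)

  # full 4-parameter polish; crossover kept strictly inside the data range
  u_min <- min(u); u_max <- max(u)
  obj <- function(par) {
    uc <- par[4]
    if (uc <= u_min || uc >= u_max) return(Inf)
    pred <- par[1] - par[2] * u - (par[3] - par[2]) * pmax(0, u - uc)
    sum((y - pred)^2)
  }
  start <- c(best$log_amplitude, best$beta1, best$beta2, uc_best)
  pol <- tryCatch(
    optim(start, obj, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (!is.null(pol) && is.finite(pol$value) && pol$value < best$rss) {
    best <- list(rss = pol$value, log_amplitude = pol$par[1],
                 beta1 = pol$par[2], beta2 = pol$par[3])
    uc_best <- pol$par[4]
  }

  n <- length(u)
  structure(
    list(beta1 = best$beta1, beta2 = best$beta2,
         crossover_frequency = 10^uc_best,
         log_amplitude = best$log_amplitude,
         rss = best$rss, n_points = n, k = 5L,
         bic = bic_from_rss(best$rss, n, 5L),
         n_dropped = pts$n_dropped),
    class = "double_powerlaw_fit"
  )
}

#' Compare single and double power-law fits by BIC
#'
#' `dbic = BIC(double) - BIC(single)`: positive values are evidence for the
#' single (scale-invariant) power law, with the conventional grades "positive
#' evidence" above 2 and "very strong" above 10 feeding the Scale Invariance
#' Index.
#'
#' @param single A `powerlaw_fit`.
#' @param double A `double_powerlaw_fit` on the same spectrum.
#' @return One-row tibble: `dbic`, `preferred` (`"single"` iff `dbic >= 0`).
#' @export
compare_models <- function(single, double) {
  if (single$n_points != double$n_points) {
    stop_critisus("Fits are not on the same spectrum (n_points differ).",
                  "critisus_validation_error")
  }
  dbic <- as.numeric(double$bic) - as.numeric(single$bic)
  tibble(dbic = dbic, preferred = if (dbic >= 0) "single" else "double")
}

#' Classify noise colour from a spectral exponent
#'
#' White for `beta <= 0.5`, pink for `0.5 < beta < 1.5` (the 1/f,
#' criticality band), brown for `beta >= 1.5`. `beta` is the magnitude of
#' the log-log spectral slope.
#'
#' @param beta Spectral exponent magnitude.
#' @return `"white"`, `"pink"` or `"brown"`.
#' @export
classify_noise <- function(beta) {
  assert_scalar_number(beta, "beta")
  if (beta <= 0.5) "white" else if (beta < 1.5) "pink" else "brown"
}
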