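#' Specify a colored-noise target
#'
#' Bundles the parameters of a Gaussian colored-noise series whose power
#' spectrum follows \eqn{S(f) \propto f^{-\beta}}: white noise has
#' \eqn{\beta = 0}, pink (1/f) noise \eqn{\beta = 1}, brown noise
#' \eqn{\beta = 2}.
#'
#' @param beta Target spectral exponent (dimensionless, >= 0).
#' @param n Number of samples (>= 64).
#' @param sigma Target sample standard deviation, in flux units (> 0).
#' @param samples_per_day Sampling rate; 48 for half-hourly records.
#' @param seed Integer RNG seed; identical specs give bit-identical series.
#'
#' @return A list of class `noise_spec`.
#' @seealso [colored_noise()], [make_site_year()]
#' @export
noise_spec <- function(beta = 1, n = 17520L, sigma = 1, samples_per_day = 48L,
                       seed = 1L) {
  assert_scalar_number(beta, "beta")
  assert_scalar_number(n, "n")
  assert_scalar_number(sigma, "sigma")
  assert_scalar_number(seed, "seed")
  if (beta < 0) stop_critisus("`beta` must be >= 0.", "critisus_validation_error")
  if (n < 64) stop_critisus("`n` must be >= 64.", "critisus_validation_error")
  if (sigma <= 0) stop_critisus("`sigma` must be > 0.", "critisus_validation_error")
  structure(
    list(beta = beta, n = as.integer(n), sigma = sigma,
         samples_per_day = as.integer(samples_per_day),
         seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Specify deterministic contamination of a synthetic flux series
#'
#' Describes the structured components superposed on colored noise by
#' [make_site_year()]: a diurnal sinusoid at 1 cycle/day with its first two
#' harmonics (2 and 3 cycles/day), an optional linear trend, and blocks of
#' missing values encoded with a sentinel, mimicking instrument outages in
#' eddy-covariance records.
#'
#' @param diurnal_amplitude Amplitude of the 1 cycle/day sinusoid (flux units).
#' @param harmonic_amplitudes Length-2 numeric: amplitudes at 2 and 3 cycles/day.
#' @param trend_slope Linear trend, flux units per sample.
#' @param gap_blocks List of `c(start, length)` pairs (1-based start indices)
#'   marking runs of samples to replace with the sentinel.
#' @param sentinel Missing-value code written in place of gap samples.
#'
#' @return A list of class `contamination_spec`.
#' @export
contamination_spec <- function(diurnal_amplitude = 0,
                               harmonic_amplitudes = c(0, 0),
                               trend_slope = 0,
                               gap_blocks = list(),
                               sentinel = -9999) {
  assert_scalar_number(diurnal_amplitude, "diurnal_amplitude")
  assert_scalar_number(trend_slope, "trend_slope")
  if (length(harmonic_amplitudes) != 2L || any(!is.finite(harmonic_amplitudes))) {
    stop_critisus("`harmonic_amplitudes` must be two finite numbers (2 and 3 cpd).",
                  "critisus_validation_error")
  }
  if (diurnal_amplitude < 0 || any(harmonic_amplitudes < 0)) {
    stop_critisus("Amplitudes must be >= 0.", "critisus_validation_error")
  }
  structure(
    list(diurnal_amplitude = diurnal_amplitude,
         harmonic_amplitudes = as.numeric(harmonic_amplitudes),
         trend_slope = trend_slope,
         gap_blocks = gap_blocks,
         sentinel = sentinel),
    class = "contamination_spec"
  )
}

#' Generate Gaussian colored noise by spectral synthesis
#'
#' Draws independent Gaussian Fourier amplitudes with standard deviation
#' proportional to \eqn{f^{-\beta/2}} and random phases (Timmer-Konig style),
#' inverse-transforms, and rescales to the requested standard deviation.
#' The zero-frequency amplitude is set to 0, so the output is exactly
#' zero-mean; the expected periodogram follows \eqn{f^{-\beta}} at every
#' Fourier frequency.
#'
#' @param spec A [noise_spec()].
#' @return Numeric vector of length `spec$n`.
#' @examples
#' x <- colored_noise(noise_spec(beta = 1, n = 1024, seed = 42))
#' sd(x)   # == 1 by construction
#' @export
colored_noise <- function(spec) {
  if (!inherits(spec, "noise_spec")) spec <- do.call(noise_spec, spec)
  n <- spec$n
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)

  f <- seq_len(n %/% 2) * spec$samples_per_day / n  # positive Fourier freqs
  amp <- f^(-spec$beta / 2)
  nf <- length(f)
  has_nyquist <- n %% 2L == 0L

  re <- rnorm(nf) * amp
  im <- rnorm(nf) * amp
  if (has_nyquist) im[nf] <- 0   # Nyquist bin is real for even n

  spec_fft <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[1] <- 0 + 0i                                # zero mean
  full[2:(nf + 1L)] <- spec_fft
  if (has_nyquist) {
    if (nf > 1L) full[n:(n - nf + 2L)] <- Conj(spec_fft[seq_len(nf - 1L)])
  } else {
    full[n:(n - nf + 1L)] <- Conj(spec_fft)
  }
  x <- Re(fft(full, inverse = TRUE)) / sqrt(n)
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop_critisus("Degenerate noise draw.", "critisus_validation_error")
  x * spec$sigma / s
}

# Seed scoped to the generator: set a local seed, return a restorer.
.Random.seed_guard <- function(seed) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", saved, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }
}

#' Simulate one site-year of half-hourly flux data
#'
#' Superposes on [colored_noise()] a linear trend, a diurnal sinusoid at
#' 1 cycle/day plus harmonics at 2 and 3 cycles/day, and replaces the
#' requested gap blocks with a sentinel, producing a table in the same layout
#' [read_flux_table()] ingests.
#'
#' @param noise A [noise_spec()].
#' @param contamination A [contamination_spec()].
#' @param site_id Site label stored with the series.
#' @param variable_name Flux variable name (column name on write).
#' @param start Timestamp of the first sample.
#'
#' @return A raw flux series: tibble with columns `timestamp` (POSIXct, UTC,
#'   30-min spacing), `value`, `missing`, and attributes `site_id`,
#'   `variable_name`, `sentinel`.
#' @examples
#' raw <- make_site_year(noise_spec(beta = 1, n = 960, seed = 3),
#'                       contamination_spec(diurnal_amplitude = 5))
#' head(raw)
#' @export
make_site_year <- function(noise,
                           contamination = contamination_spec(),
                           site_id = "SYNTH",
                           variable_name = "RECO",
                           start = as.POSIXct("2001-01-01 00:00", tz = "UTC")) {
  if (!inherits(noise, "noise_spec")) noise <- do.call(noise_spec, noise)
  if (!inherits(contamination, "contamination_spec")) {
    contamination <- do.call(contamination_spec, contamination)
  }
  n <- noise$n
  t_idx <- seq_len(n) - 1L
  x <- colored_noise(noise)

  day <- t_idx / noise$samples_per_day
  x <- x + contamination$trend_slope * t_idx +
    contamination$diurnal_amplitude * sin(2 * pi * 1 * day) +
    contamination$harmonic_amplitudes[1] * sin(2 * pi * 2 * day) +
    contamination$harmonic_amplitudes[2] * sin(2 * pi * 3 * day)

  missing <- rep(FALSE, n)
  for (blk in contamination$gap_blocks) {
    start_i <- blk[1]; len <- blk[2]
    if (start_i < 1 || len < 1 || start_i + len - 1 > n) {
      stop_critisus("Gap block outside [1, n].", "critisus_validation_error")
    }
    idx <- seq.int(start_i, length.out = len)
    if (any(missing[idx])) {
      stop_critisus("Overlapping gap blocks.", "critisus_validation_error")
    }
    missing[idx] <- TRUE
  }
  x[missing] <- contamination$sentinel

  new_raw_flux(
    tibble(
      timestamp = start + (t_idx * 1800),
      value = x,
      missing = missing
    ),
    site_id = site_id, variable_name = variable_name,
    sentinel = contamination$sentinel
  )
}

new_raw_flux <- function(df, site_id, variable_name, sentinel = -9999) {
  structure(
    as_tibble(df),
    site_id = site_id, variable_name = variable_name, sentinel = sentinel,
    class = c("raw_flux", class(as_tibble(df)))
  )
}
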