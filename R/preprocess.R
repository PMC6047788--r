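#' Notch (band-stop) filter settings
#'
#' A second-order IIR notch rejects a narrow band around `center_frequency`
#' and leaves the rest of the spectrum essentially unchanged; the -3 dB
#' bandwidth is `center_frequency / Q`.
#'
#' @param center_frequency Cycles per day; must be below the Nyquist
#'   frequency (24 cycles/day at half-hourly sampling).
#' @param Q Quality factor (> 0); larger Q = narrower notch.
#' @return List of class `notch_setting`.
#' @export
notch_setting <- function(center_frequency, Q) {
  assert_scalar_number(center_frequency, "center_frequency")
  assert_scalar_number(Q, "Q")
  if (Q <= 0) stop_critisus("`Q` must be > 0.", "critisus_validation_error")
  if (center_frequency <= 0) {
    stop_critisus("`center_frequency` must be > 0.", "critisus_validation_error")
  }
  structure(list(center_frequency = center_frequency, Q = Q),
            class = "notch_setting")
}

#' Remove a least-squares linear trend
#'
#' @param values Numeric vector, no missing values.
#' @return List with `residuals` (orthogonal to the constant and the time
#'   index), `slope` (per sample) and `intercept`.
#' @export
detrend_linear <- function(values) {
  if (anyNA(values)) {
    stop_critisus("Missing values present; apply the gap policy upstream.",
                  "critisus_precondition_error")
  }
  n <- length(values)
  if (n < 3) stop_critisus("Need >= 3 samples to detrend.", "critisus_validation_error")
  t_idx <- seq_len(n) - 1
  fit <- lm.fit(cbind(1, t_idx), values)
  list(
    residuals = unname(fit$residuals),
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1])
  )
}

# RBJ-cookbook second-order digital notch; same transfer function family as
# the classic scipy iirnotch design.
notch_coefficients <- function(center_frequency, Q, samples_per_day) {
  nyquist <- samples_per_day / 2
  if (center_frequency >= nyquist) {
    stop_critisus(
      sprintf("Notch frequency %g cpd is at/above Nyquist (%g cpd).",
              center_frequency, nyquist),
      "critisus_validation_error"
    )
  }
  w0 <- 2 * pi * center_frequency / samples_per_day
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply a zero-phase IIR notch filter
#'
#' The second-order notch is applied with zero phase by multiplying the
#' series' DFT by the filter's squared magnitude response — the circular
#' equivalent of running the filter forward and backward
#' (`filtfilt`), but free of the edge transients time-domain
#' forward-backward filtering leaves on narrowband notches. Zero phase
#' matters here because phase distortion would bias the ordinal-pattern
#' statistics computed downstream; the squared response doubles the
#' stop-band attenuation. Filters applied this way commute exactly.
#'
#' @param values Numeric vector (gap-free).
#' @param setting A [notch_setting()].
#' @param samples_per_day Sampling rate (48 for half-hourly data).
#' @return Filtered vector, same length.
#' @export
notch_filter <- function(values, setting, samples_per_day = HALF_HOURLY) {
  if (!inherits(setting, "notch_setting")) setting <- do.call(notch_setting, setting)
  co <- notch_coefficients(setting$center_frequency, setting$Q, samples_per_day)
  n <- length(values)
  w <- 2 * pi * (seq_len(n) - 1L) / n          # DFT bin frequencies, rad/sample
  z1 <- exp(complex(imaginary = -w))
  H <- (co$b[1] + co$b[2] * z1 + co$b[3] * z1^2) /
    (co$a[1] + co$a[2] * z1 + co$a[3] * z1^2)
  Re(fft(fft(values) * Mod(H)^2, inverse = TRUE)) / n
}

#' Default notch cascade: diurnal cycle and first two harmonics
#'
#' 1 cycle/day at Q = 12, then 2 and 3 cycles/day at Q = 30.
#' @return List of [notch_setting()]s.
#' @export
default_notches <- function() {
  list(notch_setting(1, 12), notch_setting(2, 30), notch_setting(3, 30))
}

#' Build the fluctuation series from a complete annual flux series
#'
#' Removes the linear trend, then notch-filters the diurnal periodicity
#' (1 cycle/day, Q = 12) and its first two harmonics (2 and 3 cycles/day,
#' Q = 30 each), in that order. The residual is the "fluctuations" series on
#' which all spectral and information-theoretic analysis runs.
#'
#' @param series A gap-free raw flux series (or plain numeric vector).
#' @param notches List of [notch_setting()]s; `NULL` disables filtering.
#' @param samples_per_day Sampling rate.
#' @return Tibble of class `fluctuation_series` with column `value`, and
#'   attributes `samples_per_day` and `provenance` (trend removed, notch
#'   settings applied).
#' @export
make_fluctuations <- function(series, notches = default_notches(),
                              samples_per_day = HALF_HOURLY) {
  if (is.data.frame(series)) {
    if (any(series$missing)) {
      stop_critisus("Series has gaps; only gap-free years are analysed.",
                    "critisus_precondition_error")
    }
    values <- series$value
  } else {
    values <- as.numeric(series)
  }
  det <- detrend_linear(values)
  x <- det$residuals
  for (ns in notches) x <- notch_filter(x, ns, samples_per_day)
  structure(
    tibble(value = x),
    samples_per_day = samples_per_day,
    provenance = list(
      trend_slope = det$slope,
      trend_intercept = det$intercept,
      notches = lapply(notches, function(ns) {
        c(center_frequency = ns$center_frequency, Q = ns$Q)
      }),
      filter_family = "RBJ biquad notch, zero-phase (squared-magnitude DFT application)"
    ),
    class = c("fluctuation_series", class(tibble(value = x)))
  )
}
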