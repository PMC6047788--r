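# Shared fixture builders. All synthetic inputs are generated in code.

# power_spectrum object with exactly known power values
make_ps <- function(frequency, power, n_series = 2L * length(frequency)) {
  structure(
    tibble::tibble(frequency = frequency, power = power),
    n_series = n_series, samples_per_day = 48,
    class = c("power_spectrum", class(tibble::tibble()))
  )
}

# frequencies of a year-like grid (n samples at 48/day), cycles/day
year_freqs <- function(n = 8192) seq_len(n %/% 2) * 48 / n

# independent spectral-exponent oracle: mean log-log slope of spec.pgram
# periodograms (stats machinery only, no critisus fitting path)
oracle_beta <- function(series_list) {
  slopes <- vapply(series_list, function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = 48), taper = 0,
                            detrend = FALSE, fast = FALSE, plot = FALSE)
    keep <- sp$spec > 0
    -unname(stats::coef(stats::lm(log10(sp$spec[keep]) ~ log10(sp$freq[keep])))[2])
  }, numeric(1))
  mean(slopes)
}

# ordinal distribution with hand-set probabilities (valid object, known p)
dist_with_probs <- function(p, D = NULL) {
  D <- D %||% match(length(p), factorial(1:8))
  d <- ordinal_distribution(seq_len(D * 2 + 5) + 0.1 * sin(seq_len(D * 2 + 5)), D = D)
  d$probabilities <- p
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
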