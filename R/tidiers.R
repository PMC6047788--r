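#' Tidy a single power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("log_amplitude", "beta"),
    estimate = c(x$log_amplitude, x$beta)
  )
}

#' @rdname tidy.powerlaw_fit
#' @export
tidy.double_powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("log_amplitude", "beta1", "beta2", "crossover_frequency"),
    estimate = c(x$log_amplitude, x$beta1, x$beta2, x$crossover_frequency)
  )
}

#' One-row fit summary for power-law fits
#'
#' @param x A `powerlaw_fit` or `double_powerlaw_fit`.
#' @param ... Unused.
#' @return Tibble: `rss`, `n_points`, `k`, `bic`.
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(rss = x$rss, n_points = x$n_points, k = x$k, bic = as.numeric(x$bic))
}

#' @rdname glance.powerlaw_fit
#' @export
glance.double_powerlaw_fit <- glance.powerlaw_fit

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Single power law: S(f) ~ f^-%.3f  (rss %.4g over %d points, BIC %.1f)\n",
              x$beta, x$rss, x$n_points, as.numeric(x$bic)))
  invisible(x)
}

#' @export
print.double_powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Broken power law: beta1 %.3f | beta2 %.3f, crossover %.3g cpd  (rss %.4g, BIC %.1f)\n",
    x$beta1, x$beta2, x$crossover_frequency, x$rss, as.numeric(x$bic)))
  invisible(x)
}
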