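#' Log-log periodogram plot with optional power-law fits
#'
#' @param object A `power_spectrum`.
#' @param single Optional `powerlaw_fit` to overlay.
#' @param double Optional `double_powerlaw_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, single = NULL, double = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (cycles/day)", y = "spectral density",
                  title = "Fluctuation periodogram")
  if (!is.null(single)) {
    df <- tibble(frequency = object$frequency,
                 power = 10^(single$log_amplitude - single$beta * log10(object$frequency)))
    p <- p + ggplot2::geom_line(data = df, colour = "firebrick")
  }
  if (!is.null(double)) {
    u <- log10(object$frequency)
    uc <- log10(double$crossover_frequency)
    yhat <- double$log_amplitude - double$beta1 * u -
      (double$beta2 - double$beta1) * pmax(0, u - uc)
    df <- tibble(frequency = object$frequency, power = 10^yhat)
    p <- p + ggplot2::geom_line(data = df, colour = "steelblue")
  }
  p
}

#' Complexity-entropy plane
#'
#' Scatter of (H, C) points with the fitted quadratic `C = a H (1 - H)`
#' overlaid when supplied.
#'
#' @param points Data frame with columns `H` and `C` (e.g. rows of
#'   site-year reports).
#' @param fit Optional result of [fit_entropy_complexity()].
#' @return A ggplot.
#' @export
plot_entropy_complexity <- function(points, fit = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(.data$H, .data$C)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "permutation entropy H", y = "statistical complexity C",
                  title = "Complexity-entropy plane")
  if (!is.null(fit)) {
    grid <- tibble(H = seq(0, 1, length.out = 200))
    grid$C <- fit$a * grid$H * (1 - grid$H)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Fisher-information evolution for one site
#'
#' @param object A `fisher_trajectory` from [fisher_evolution()].
#' @param ... Unused.
#' @return A ggplot; points coloured by per-year noise class, with segment
#'   means drawn when the trajectory carries them.
#' @export
autoplot.fisher_trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$year, .data$F)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$noise_class), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(white = "skyblue3", pink = "hotpink3", brown = "tan4")
    ) +
    ggplot2::labs(x = "year", y = "Fisher information",
                  title = paste("Fisher evolution:", attr(object, "site_id")),
                  colour = "noise")
  seg <- attr(object, "segment_means")
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_hline(yintercept = seg$mean_F, linetype = "dashed")
  }
  p
}
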