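#' Three-point finite-difference derivatives
#'
#' Nonuniform three-point stencil for first and second derivatives at the
#' interior points of a sampled signal, with `alpha` the ratio of the
#' spacing to the previous point over the spacing to the following point.
#' For evenly spaced samples (`alpha = 1`) this reduces to central
#' differences, `x' = (x[i+1] - x[i-1]) / (2 dt)` and
#' `x'' = (x[i+1] - 2 x[i] + x[i-1]) / dt^2`, which are exact for
#' quadratics. Endpoints are excluded.
#'
#' @param x Numeric vector, >= 3 points.
#' @param dt Sampling step (> 0), the spacing to the following point.
#' @param alpha Spacing ratio (> 0); the previous point sits `alpha * dt`
#'   behind.
#' @return List with `first` and `second`, each of length `length(x) - 2`.
#' @export
three_point_derivatives <- function(x, dt, alpha = 1) {
  assert_scalar_number(dt, "dt")
  assert_scalar_number(alpha, "alpha")
  if (dt <= 0) stop_critisus("`dt` must be > 0.", "critisus_validation_error")
  if (alpha <= 0) stop_critisus("`alpha` must be > 0.", "critisus_validation_error")
  n <- length(x)
  if (n < 3) stop_critisus("Need >= 3 points.", "critisus_validation_error")
  i <- 2:(n - 1)
  xp <- x[i + 1L]; x0 <- x[i]; xm <- x[i - 1L]
  denom <- alpha * (alpha + 1) * dt
  list(
    first = (alpha^2 * xp - xm - (alpha^2 - 1) * x0) / denom,
    second = 2 * (alpha * xp + xm - (alpha + 1) * x0) / (denom * dt)
  )
}

#' Tangential speed and acceleration along a phase-space trajectory
#'
#' For a trajectory of `m` state variables sampled at constant step `dt`,
#' computes the tangential speed
#' \eqn{s'(t) = \sqrt{\sum_i (dx_i/dt)^2}} and the tangential acceleration
#' \eqn{s''(t) = (1/s') \sum_i (dx_i/dt)(d^2x_i/dt^2)} at the interior
#' sample points. Where `s' = 0` the acceleration is undefined and returned
#' as `NaN`.
#'
#' @param states Numeric vector (m = 1) or matrix / data frame with one
#'   column per state variable.
#' @param dt Sampling step.
#' @param alpha Spacing ratio passed to [three_point_derivatives()].
#' @return Tibble with columns `s_prime` and `s_dprime`, `n - 2` rows.
#' @export
tangential_kinematics <- function(states, dt, alpha = 1) {
  X <- as.matrix(states)
  storage.mode(X) <- "double"
  if (nrow(X) < 3) stop_critisus("Need >= 3 points.", "critisus_validation_error")
  d1 <- matrix(0, nrow(X) - 2L, ncol(X))
  d2 <- d1
  for (j in seq_len(ncol(X))) {
    dj <- three_point_derivatives(X[, j], dt, alpha)
    d1[, j] <- dj$first
    d2[, j] <- dj$second
  }
  sp <- sqrt(rowSums(d1^2))
  sdp <- rowSums(d1 * d2) / sp   # NaN where sp == 0 (flagged downstream)
  tibble(s_prime = sp, s_dprime = sdp)
}

#' Phase-space Fisher information of a trajectory
#'
#' Discretizes \eqn{I = (1/T) \int_0^T s''^2 / s'^4 \, dt} over the
#' trajectory's tangential kinematics. Points where the speed falls below a
#' floor (`floor_mult` times the median speed) are dropped and counted,
#' guarding the \eqn{s'^{-4}} singularity; the normalising duration `T` is
#' the time spanned by the points actually summed. Constant-velocity motion
#' (including uniform circular motion) has `s'' = 0` and hence `I = 0`;
#' stable dynamic regimes keep `I` constant over time.
#'
#' @param states Numeric vector, matrix or data frame of state variables.
#' @param dt Sampling step.
#' @param window Duration to analyse from the start of the trajectory;
#'   default the whole trajectory.
#' @param floor_mult Speed-floor multiplier applied to the median speed.
#' @param alpha Spacing ratio for the difference stencil.
#' @return One-row tibble: `I`, `T` (duration used), `n_used`,
#'   `dropped_points`, and list-columns `s_prime`, `s_dprime`.
#' @export
phase_fisher_information <- function(states, dt, window = NULL,
                                     floor_mult = 1e-8, alpha = 1) {
  if (is.data.frame(states) && "value" %in% names(states)) states <- states$value
  X <- as.matrix(states)
  duration <- (nrow(X) - 1) * dt
  if (!is.null(window)) {
    assert_scalar_number(window, "window")
    if (window > duration + 1e-12) {
      stop_critisus("`window` exceeds the trajectory duration.",
                    "critisus_validation_error")
    }
    n_keep <- max(3L, as.integer(floor(window / dt)) + 1L)
    X <- X[seq_len(min(nrow(X), n_keep)), , drop = FALSE]
  }
  kin <- tangential_kinematics(X, dt, alpha)
  floor_val <- floor_mult * stats::median(kin$s_prime)
  use <- kin$s_prime > floor_val & is.finite(kin$s_dprime)
  dropped <- sum(!use)
  if (!any(use)) {
    stop_critisus("All points below the speed floor: trajectory is effectively stationary.",
                  "critisus_validation_error")
  }
  T_used <- sum(use) * dt
  I <- sum(kin$s_dprime[use]^2 / kin$s_prime[use]^4) * dt / T_used
  tibble(
    I = I, T = T_used, n_used = sum(use), dropped_points = dropped,
    s_prime = list(kin$s_prime), s_dprime = list(kin$s_dprime)
  )
}
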