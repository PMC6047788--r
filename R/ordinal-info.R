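#' Bandt-Pompe ordinal pattern distribution
#'
#' Slides a window of `D` values with delay `tau` over the series; each
#' window is mapped to the permutation that sorts it ascending (ties broken
#' by first occurrence), and relative frequencies are tallied over all
#' `n - (D - 1) * tau` windows. Patterns are kept in a fixed canonical
#' order: lexicographic over the permutation tuples. Because the statistics
#' depend only on order relations, they are invariant under any strictly
#' monotone transform of the values.
#'
#' @param values Numeric vector; `length(values) >= D * tau + 1` and not
#'   constant.
#' @param D Embedding dimension (>= 2); default 4 gives 24 patterns,
#'   comfortably below the annual sample count of 17,520.
#' @param tau Embedding delay (>= 1).
#' @return Object of class `ordinal_distribution`: `probabilities`
#'   (length `factorial(D)`, canonical order), `patterns` (list of tuples),
#'   `D`, `tau`, `n_windows`, `tie_count`.
#' @export
ordinal_distribution <- function(values, D = 4L, tau = 1L) {
  values <- as.numeric(values)
  D <- as.integer(D); tau <- as.integer(tau)
  if (D < 2L) stop_critisus("`D` must be >= 2.", "critisus_validation_error")
  if (tau < 1L) stop_critisus("`tau` must be >= 1.", "critisus_validation_error")
  n <- length(values)
  if (n < D * tau + 1L) {
    stop_critisus("Series too short for the requested embedding.",
                  "critisus_validation_error")
  }
  if (anyNA(values)) {
    stop_critisus("Missing values present.", "critisus_precondition_error")
  }
  if (max(values) == min(values)) {
    stop_critisus("Constant series: ordinal patterns are degenerate.",
                  "critisus_validation_error")
  }

  m <- n - (D - 1L) * tau
  # window matrix: W[i, j] = values[i + (j-1)*tau]
  W <- vapply(seq_len(D), function(j) values[seq_len(m) + (j - 1L) * tau],
              numeric(m))
  if (m == 1L) W <- matrix(W, nrow = 1L)

  # ranks with first-occurrence tie-break, vectorised over windows
  R <- matrix(1L, m, D)
  ties <- 0L
  for (j in seq_len(D)) {
    for (k in seq_len(D)) {
      if (k == j) next
      eq <- W[, k] == W[, j]
      ties <- ties + sum(eq)
      R[, j] <- R[, j] + (W[, k] < W[, j]) + (k < j & eq)
    }
  }
  ties <- ties %/% 2L  # each tied pair counted twice

  # sorting permutation pi = inverse of the rank vector
  P <- matrix(0L, m, D)
  P[cbind(rep(seq_len(m), D), as.vector(R))] <- rep(seq_len(D), each = m)

  # Lehmer code -> lexicographic index of each permutation tuple
  idx <- rep(1L, m)
  for (i in seq_len(D - 1L)) {
    smaller_after <- rep(0L, m)
    for (j in (i + 1L):D) smaller_after <- smaller_after + (P[, j] < P[, i])
    idx <- idx + smaller_after * factorial(D - i)
  }

  M <- factorial(D)
  counts <- tabulate(idx, nbins = M)
  structure(
    list(probabilities = counts / m,
         patterns = all_permutations(D),
         D = D, tau = tau, n_windows = m, tie_count = ties),
    class = "ordinal_distribution"
  )
}

# all permutations of 1:D in lexicographic order
all_permutations <- function(D) {
  if (D == 1L) return(list(1L))
  out <- list()
  for (first in seq_len(D)) {
    rest <- all_permutations(D - 1L)
    remaining <- setdiff(seq_len(D), first)
    out <- c(out, lapply(rest, function(p) c(first, remaining[p])))
  }
  out
}

check_ordinal <- function(dist) {
  if (!inherits(dist, "ordinal_distribution")) {
    stop_critisus("Expected an `ordinal_distribution`.", "critisus_validation_error")
  }
  invisible(dist)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal pattern distribution divided by its
#' maximum `log(D!)`: 0 for a fully ordered (monotone) series, 1 for a
#' series whose patterns are equiprobable (e.g. iid noise). Used as the
#' stability measure in the Sustainability Index.
#'
#' @param dist An [ordinal_distribution()].
#' @return Value in \[0, 1\].
#' @export
permutation_entropy <- function(dist) {
  check_ordinal(dist)
  shannon(dist$probabilities) / log(length(dist$probabilities))
}

#' MPR statistical complexity
#'
#' `C = Q_J * H`: the Jensen-Shannon disequilibrium between the pattern
#' distribution and the uniform distribution (normalized by its maximum over
#' distributions on `D!` symbols) times the normalized permutation entropy.
#' Vanishes both at perfect order (`H = 0`) and full randomness (uniform
#' patterns), and is maximal in between — where 1/f dynamics live.
#'
#' @param dist An [ordinal_distribution()].
#' @return Value in \[0, 1\].
#' @export
statistical_complexity <- function(dist) {
  check_ordinal(dist)
  p <- dist$probabilities
  M <- length(p)
  u <- rep(1 / M, M)
  js <- shannon((p + u) / 2) - shannon(p) / 2 - shannon(u) / 2
  q0 <- -2 / (((M + 1) / M) * log(M + 1) - 2 * log(2 * M) + log(M))
  h <- shannon(p) / log(M)
  q0 * js * h
}

#' Ordinal Fisher information
#'
#' Discrete Fisher measure over the canonically ordered pattern
#' probabilities: `F = F0 * sum_i (sqrt(p[i+1]) - sqrt(p[i]))^2`, with
#' `F0 = 1` when all mass sits on the first or last pattern and `1/2`
#' otherwise, so `F` lies in \[0, 1\]. Sensitive to local gradients of the
#' distribution; 0 for the uniform distribution. The value depends on the
#' canonical (lexicographic) pattern order, which is recorded with every
#' report; the symmetric sum makes it invariant to reversing that order.
#'
#' @param dist An [ordinal_distribution()].
#' @return Value in \[0, 1\].
#' @export
ordinal_fisher <- function(dist) {
  check_ordinal(dist)
  p <- dist$probabilities
  M <- length(p)
  f0 <- if (p[1] == 1 || p[M] == 1) 1 else 0.5
  f0 * sum(diff(sqrt(p))^2)
}

#' Compute all ordinal information measures at once
#'
#' @param values Numeric vector (fluctuation series).
#' @param D,tau Embedding dimension and delay.
#' @return One-row tibble: `H`, `C`, `F`, `D`, `tau`, `pattern_count`,
#'   `tie_count`.
#' @export
info_measures <- function(values, D = 4L, tau = 1L) {
  if (is.data.frame(values)) values <- values$value
  dist <- ordinal_distribution(values, D, tau)
  tibble(
    H = permutation_entropy(dist),
    C = statistical_complexity(dist),
    F = ordinal_fisher(dist),
    D = dist$D, tau = dist$tau,
    pattern_count = length(dist$probabilities),
    tie_count = dist$tie_count
  )
}

#' Fit the quadratic complexity-entropy relation
#'
#' Fits `C = a * H * (1 - H)` by least squares over a set of (H, C) points
#' — the single-parameter quadratic relation the complexity-entropy plane of
#' colored-noise ensembles traces out.
#'
#' @param points Data frame with columns `H` and `C` (>= 5 rows, H not all
#'   equal).
#' @return One-row tibble of class `quadratic_fit`: `a`, `r_squared`.
#' @export
fit_entropy_complexity <- function(points) {
  if (!all(c("H", "C") %in% names(points))) {
    stop_critisus("`points` needs columns `H` and `C`.", "critisus_validation_error")
  }
  H <- points$H; C <- points$C
  if (length(H) < 5) {
    stop_critisus("Need >= 5 points.", "critisus_validation_error")
  }
  if (length(unique(H)) < 2) {
    stop_critisus("Degenerate H values (all equal).", "critisus_validation_error")
  }
  x <- H * (1 - H)
  if (sum(x^2) == 0) {
    stop_critisus("All H at 0 or 1: quadratic relation unidentifiable.",
                  "critisus_validation_error")
  }
  a <- sum(C * x) / sum(x^2)
  rss <- sum((C - a * x)^2)
  tss <- sum((C - mean(C))^2)
  r2 <- if (tss == 0) as.numeric(rss < 1e-24) else max(0, min(1, 1 - rss / tss))
  structure(
    tibble(a = a, r_squared = r2),
    class = c("quadratic_fit", class(tibble(a = a)))
  )
}
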