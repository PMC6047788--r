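#' Criticality Index
#'
#' Piecewise-linear distance to 1/f (pink-noise) dynamics: 0 for
#' `beta <= 0.5`, rising as `2*beta - 1` to its peak of 1 at `beta = 1`,
#' falling as `-2*beta + 3`, and 0 again for `beta >= 1.5`. An ecosystem
#' loses criticality either by drifting to white noise (loss of memory /
#' robustness) or to brown noise (loss of adaptability).
#'
#' @param beta Spectral exponent magnitude (finite).
#' @return Value in \[0, 1\].
#' @examples
#' criticality_index(1)     # 1, the 1/f case
#' criticality_index(0.75)  # 0.5
#' @export
criticality_index <- function(beta) {
  assert_scalar_number(beta, "beta")
  if (beta <= 0.5 || beta >= 1.5) 0
  else if (beta <= 1) 2 * beta - 1
  else -2 * beta + 3
}

#' Scale Invariance Index
#'
#' Maps the BIC difference `dbic = BIC(double) - BIC(single)` to \[0, 1\]:
#' 0 for `dbic <= 2`, 1 for `dbic >= 10`, linear (`(dbic - 2) / 8`)
#' in between — i.e. the index saturates once the evidence for a single
#' scale-free power law is very strong.
#'
#' @param dbic BIC difference (finite).
#' @return Value in \[0, 1\].
#' @examples
#' scale_invariance_index(12)  # 1
#' scale_invariance_index(6)   # 0.5
#' @export
scale_invariance_index <- function(dbic) {
  assert_scalar_number(dbic, "dbic")
  min(1, max(0, (dbic - 2) / 8))
}

#' Ecosystemic Health Index
#'
#' Geometric mean of criticality and scale invariance (the functional form
#' of the Human Development Index): `sqrt(icrit * iscale)`.
#'
#' @param icrit Criticality Index in \[0, 1\].
#' @param iscale Scale Invariance Index in \[0, 1\].
#' @return Value in \[0, 1\].
#' @export
health_index <- function(icrit, iscale) {
  assert_unit_interval(icrit, "icrit")
  assert_unit_interval(iscale, "iscale")
  sqrt(icrit * iscale)
}

#' Sustainability Index
#'
#' Geometric mean of health and stability: `sqrt(ih * stability)`, with
#' stability the normalized permutation entropy of the fluctuation series.
#'
#' @param ih Ecosystemic Health Index in \[0, 1\].
#' @param stability Normalized permutation entropy in \[0, 1\].
#' @return Value in \[0, 1\].
#' @export
sustainability_index <- function(ih, stability) {
  assert_unit_interval(ih, "ih")
  assert_unit_interval(stability, "stability")
  sqrt(ih * stability)
}
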