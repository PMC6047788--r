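---
title: "Criticality, stability and the Sustainability Index for flux time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality, stability and the Sustainability Index for flux time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critisus)
```

## The idea

Healthy ecosystems, like healthy hearts, are conjectured to operate near
criticality: their physiological signals fluctuate with a scale-invariant
1/f ("pink") power spectrum, balancing the rigidity of strongly correlated
(brown, $\beta \approx 2$) dynamics against the memorylessness of white
noise ($\beta \approx 0$). critisus quantifies this for half-hourly
eddy-covariance CO$_2$ flux records (AmeriFlux-style tables): each complete
calendar year of data yields a spectral *health* diagnosis and an
information-theoretic *stability* diagnosis, composed into a single
Sustainability Index.

## From raw fluxes to "fluctuations"

Spectral estimation needs evenly spaced, gap-free input, and small-gap
interpolation distorts exactly the high-frequency tail we fit. The gap
policy is therefore strict: only calendar years with **zero** missing
samples (17,520 half-hours; 17,568, or a record truncated to 17,520, in
leap years) are analysed. `segment_by_year()` and `select_complete_years()`
implement this.

Each complete year is then reduced to its residual "fluctuations":

1. **Linear detrend** — ordinary least squares on the sample index; a
   trendless series is left essentially unchanged.
2. **Notch cascade** — the diurnal cycle at 1 cycle/day is removed with a
   second-order IIR band-stop of quality factor $Q = 12$, and its first two
   harmonics (2 and 3 cycles/day) with narrower notches at $Q = 30$.
   "First two harmonics" is read as $\{2, 3\}$ cycles/day — the overtones
   of the daily fundamental; the cascade is configurable if a user prefers
   $\{2, 4\}$.

The notch is applied with **zero phase**: the series' DFT is multiplied by
the biquad's squared magnitude response, the circular equivalent of running
the filter forward and backward. We chose this over time-domain
forward–backward filtering after observing that, for notches this narrow
(impulse responses decaying over hundreds of samples), `filtfilt`-style
edge transients leak residual tone power, shift the series mean, and make
the harmonic notches non-commuting at the $10^{-4}$ level. The DFT
application removes the injected tones to below the neighbouring
background, preserves the zero mean exactly, and commutes exactly; its
circular-boundary assumption is benign because the response is unity
outside three narrow bands. Phase fidelity matters downstream: phase
distortion would scramble the rank orderings on which the ordinal
statistics are built.

## The spectral layer: criticality and scale invariance

`periodogram()` computes the one-sided FFT periodogram in cycles/day,
normalised so that $\sum S(f_k)\,\Delta f$ equals the series variance
(checked to 1% in the tests). Two models are fitted to
$\log_{10} S$ vs $\log_{10} f$ over all positive Fourier frequencies
(no log-binning by default — the simplest faithful reading of a
least-squares line through the logarithmic spectrum; `bin_spectrum_log()`
offers the smoothed variant):

* **Single power law** $S \propto f^{-\beta_0}$: OLS; $\beta_0$ is the
  negative slope. $\beta$ is always stored as a magnitude, so pink noise is
  $\beta = 1$ regardless of sign conventions.
* **Broken power law**: slope $-\beta_1$ below a crossover frequency,
  $-\beta_2$ above, continuous at the crossover. Given the crossover the
  model is linear, so we profile it: 20 log-spaced candidates between the
  5th and 95th percentile frequencies, hinge OLS at each, local refinement
  around the best candidate, then a Nelder–Mead polish of all four
  parameters with the crossover constrained strictly inside the fitted
  range. Because the hinge regression contains the single-law solution as
  a subspace, the double fit's RSS can never exceed the single fit's — a
  nesting guarantee the tests enforce on random spectra.

The models are compared with
$\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n$, counting the error
variance among the parameters ($k = 3$ single, $k = 5$ double), with $n$
the number of spectrum points. We define
$d\mathrm{BIC} = \mathrm{BIC}_{\text{double}} - \mathrm{BIC}_{\text{single}}$,
so large positive values mean the extra break is unwarranted — the
spectrum is scale-invariant. (The opposite subtraction order appears in
some descriptions of this construction, but it would drive the Scale
Invariance Index *down* exactly when a single scale-free law wins; the
orientation used here is the one consistent with the index's endpoints and
with the conventional BIC evidence grades of 2 and 10.)

Three published maps turn the diagnostics into indices:

* **Criticality**: $I_{crit}(\beta)$ is the piecewise-linear tent equal to
  $2\beta - 1$ on $(0.5, 1]$ and $-2\beta + 3$ on $(1, 1.5)$, zero outside,
  peaking at 1 for $\beta = 1$. The boundaries are closed (the index is 0
  *at* $\beta = 0.5$ and $1.5$), keeping it continuous. (A published
  intermediate form of the scale map, $(1/8)d\mathrm{BIC} - 1.75$, fails
  its own stated endpoints — it gives $-1.5$ at $d\mathrm{BIC} = 2$ — and
  is treated as a typo for $(d\mathrm{BIC} - 2)/8$.)
* **Scale invariance**: $I_{scale} = \min(1, \max(0, (d\mathrm{BIC}-2)/8))$.
* **Health**: $I_h = \sqrt{I_{crit} \cdot I_{scale}}$, the geometric-mean
  form of the Human Development Index.

Noise colour is classified purely from $\beta_0$: white $\le 0.5$, pink in
$(0.5, 1.5)$, brown $\ge 1.5$.

## The stability layer: ordinal information measures

Bandt–Pompe statistics are computed on the same fluctuation series with
embedding dimension $D = 4$ and delay $\tau = 1$ (defaults; $4! = 24$
patterns against 17,519 windows comfortably satisfies the $n \gg D!$
rule). Each window maps to the permutation sorting it ascending; ties are
broken by first occurrence (flux data are continuous, so ties are rare —
the count is reported). Patterns are kept in lexicographic order, and the
resulting distribution feeds:

* **Permutation entropy** $H = -\sum p \ln p / \ln D!$ — the stability
  measure: near 1 for white and pink noise, falling as spectra steepen.
* **MPR statistical complexity** $C = Q_J \cdot H$, with $Q_J$ the
  Jensen–Shannon disequilibrium to the uniform pattern distribution,
  normalised by its maximum. $C$ vanishes at both perfect order and full
  randomness; across the colored-noise family it traces the quadratic arc
  $C \approx a\,H(1-H)$, which `fit_entropy_complexity()` fits by least
  squares (the ensemble in the tests attains $r^2 \approx 0.99$).
* **Ordinal Fisher information**
  $F = F_0 \sum_i (\sqrt{p_{i+1}} - \sqrt{p_i})^2$, $F_0 = 1$ if all mass
  sits on the first or last pattern and $1/2$ otherwise, so $F \in [0,1]$.
  $F$ depends on the canonical pattern order (recorded in every report);
  the symmetric sum makes it invariant to reversing that order.

A second, phase-space Fisher information
$I = \frac{1}{T}\int_0^T s''^2 / s'^4 \, dt$ is computed from the
trajectory's tangential speed $s'$ and acceleration $s''$, estimated by
three-point differencing (the nonuniform stencil reduces to central
differences for evenly spaced samples and is exact for quadratics —
printed versions of these stencils with inconsistent subscripts were
regularised to that standard form). The integrand is singular where
$s' \to 0$, and no guard is prescribed in the source framework, so points
with speed below $10^{-8}\times$ the median speed are dropped and counted.
"One cycle" $T$ has no natural definition for ecosystem data; we use
per-year windows, so multi-year trajectories (`fisher_evolution()`) can be
read against the sustainability hypothesis that stable systems neither
gain nor lose Fisher information. The phase-space $I$ is not normalised to
$[0,1]$ and is reported separately from the ordinal $F$; the two are never
mixed. Note that $I$ is invariant under a pure rescaling of time (the
$c^4$ factors from $s''^2$ and $s'^4$ cancel), which the tests verify.

## The Sustainability Index

For each site-year, `analyze_site_year()` composes
$S = \sqrt{I_h \cdot H}$ — health from the spectral layer, stability as
normalized permutation entropy (the entropy is the stability axis
throughout the source framework's site comparisons). All indices live in
$[0,1]$ and the geometric mean annihilates: a site scores zero if either
layer does.

## What the synthetic generator emulates — and what it does not

`colored_noise()` synthesises Gaussian noise with an exact expected
$f^{-\beta}$ spectrum by drawing independent Fourier amplitudes scaled by
$f^{-\beta/2}$ with random phases and inverse transforming (Timmer–König
style), zeroing the DC bin and rescaling to the target standard deviation.
`make_site_year()` adds what the preprocessing must remove — a diurnal
sinusoid with two harmonics, a linear trend, sentinel-coded gap blocks —
at half-hourly timestamps. Defaults (n = 17,520, $\sigma = 1$, clean
contamination) mirror one complete analysis year.

Real eddy-covariance data differ in ways the generator deliberately does
not model: non-Gaussian bursts, seasonal amplitude modulation of the
diurnal cycle, weather-driven synoptic variability, u*-filtering artefacts
and instrument-specific noise. Passing tests therefore demonstrate that
the *pipeline* recovers known spectral and ordinal structure, not that any
particular field site is healthy.

Two numerical behaviours of the faithful pipeline are worth knowing.
First, least-squares detrending of steep-spectrum series ($\beta \gtrsim
2$) removes genuine low-frequency power and biases the fitted exponent
toward smaller values (a $\beta = 2.5$ year typically fits near 1.8); the
brown classification is unaffected, but absolute exponents above ~2 should
be read as lower bounds. The same flattening gives synthetic single-law
years a genuine low-frequency break, so the broken-law model often wins
the BIC comparison on *processed* synthetic spectra ($d\mathrm{BIC} < 2$,
hence $I_{scale} = 0$) even though, on raw colored-noise periodograms, the
single law is preferred in well over 90% of cases. Second, because the
periodogram's Fourier
frequencies crowd toward the Nyquist end on a log axis, the single-law fit
is dominated by high frequencies; this is the plain reading of the method
and is left as is.

## Problem sizes and determinism

All stochastic checks fix their seeds. The test ensembles use series of
4,096–17,520 samples and 5–20 replicates per condition — sizes at which
the spectral-recovery error (±0.15 on $\beta$), the quadratic-arc fit
($r^2 \ge 0.7$) and the classification rates (≥80%) are stable from seed
to seed while the whole suite runs in well under a minute. The generator
is bit-reproducible given a spec; `analyze_site_year()` is deterministic
given input and config, and the CLI's JSON reports are byte-identical
across re-runs (a config hash, not a wall-clock stamp, provides
provenance).

## Known limitations

* Gap-free-year selection discards most real site-years; that is the
  method's stated trade-off, not a bug.
* The exponent bias from detrending steep spectra (above).
* Ordinal measures with $D = 4$, $\tau = 1$ probe half-hour-scale
  ordering only; multiscale or amplitude-weighted variants are out of
  scope.
* Management metadata (e.g. excluding intensively managed cropland) must
  be supplied by the user; the pipeline never infers land condition or
  management from the flux series.
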