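Package: critisus
Title: Criticality-Based Health and Information-Theoretic Stability of Ecosystem Flux Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses ecosystem sustainability from half-hourly eddy-covariance
    flux time series. Annual series are detrended, the diurnal cycle and its
    harmonics are removed with zero-phase IIR notch filters, and the residual
    "fluctuations" are characterised by their power spectrum: a single and a
    broken (double) power law are fitted in log-log space and compared by BIC,
    yielding a spectral exponent, a noise colour (white/pink/brown), a
    Criticality Index peaking at 1/f dynamics, and a Scale Invariance Index.
    A stability layer computes Bandt-Pompe ordinal statistics (permutation
    entropy, MPR statistical complexity, ordinal Fisher information) and a
    phase-space Fisher information from three-point differencing. Health
    (sqrt(criticality x scale invariance)) and Sustainability
    (sqrt(health x stability)) indices compose the layers. Includes a
    spectral-synthesis generator of colored-noise flux surrogates with
    diurnal structure, trends and gaps, an AmeriFlux-style CSV reader, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
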