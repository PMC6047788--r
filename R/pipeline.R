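#' Default analysis configuration
#'
#' Every tunable of the per-site-year pipeline, overridable as a whole or
#' per key: flux variable, missing sentinel, notch cascade
#' (1 cpd at Q = 12; 2 and 3 cpd at Q = 30), ordinal embedding (D = 4,
#' tau = 1), phase-Fisher speed floor and stencil ratio, and the optional
#' log-binned spectrum variant.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `critisus_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    variable = "RECO",
    sentinel = -9999,
    samples_per_day = HALF_HOURLY,
    notches = default_notches(),
    D = 4L,
    tau = 1L,
    phase_floor_mult = 1e-8,
    phase_alpha = 1,
    spectrum_log_bin = FALSE,
    spectrum_bins_per_decade = 20L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop_critisus(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")),
                  "critisus_validation_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "critisus_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Average a periodogram into logarithmically spaced frequency bins
#'
#' Optional smoothing variant for the power-law fits; the default pipeline
#' fits the raw periodogram.
#'
#' @param spectrum A `power_spectrum`.
#' @param bins_per_decade Number of bins per factor-of-10 in frequency.
#' @return A `power_spectrum` with bin-mean frequencies and powers.
#' @export
bin_spectrum_log <- function(spectrum, bins_per_decade = 20L) {
  lf <- log10(spectrum$frequency)
  edges <- seq(min(lf), max(lf) + 1e-12,
               by = 1 / bins_per_decade)
  bin <- findInterval(lf, edges, rightmost.closed = TRUE)
  agg <- dplyr::summarise(
    dplyr::group_by(tibble(bin = bin, frequency = spectrum$frequency,
                           power = spectrum$power), .data$bin),
    frequency = mean(.data$frequency), power = mean(.data$power),
    .groups = "drop"
  )
  structure(
    tibble(frequency = agg$frequency, power = agg$power),
    n_series = attr(spectrum, "n_series"),
    samples_per_day = attr(spectrum, "samples_per_day"),
    class = class(spectrum)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_critisus(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                  "critisus_stage_error")
  })
}

#' Analyse one complete site-year of flux data
#'
#' Runs the full pipeline on a gap-free annual series: fluctuation
#' extraction (detrend + notch cascade), periodogram, single and double
#' power-law fits, BIC comparison, noise classification, criticality /
#' scale-invariance / health indices, ordinal information measures,
#' phase-space Fisher information, and the Sustainability Index
#' `sqrt(health x entropy)`. Deterministic given the input and config.
#'
#' @param raw A gap-free raw flux series (one calendar year).
#' @param config A [default_config()].
#' @return One-row tibble (`site_year_report`): `site_id`, `year`, `beta0`,
#'   `beta1`, `beta2`, `crossover`, `dbic`, `noise_class`, `icrit`,
#'   `iscale`, `ih`, `H`, `C`, `F_ordinal`, `I_phase`, `s_index`,
#'   `n_samples`, `tie_count`, `config_hash`.
#' @examples
#' \donttest{
#' raw <- make_site_year(noise_spec(beta = 1, n = 17520, seed = 1))
#' analyze_site_year(raw)
#' }
#' @export
analyze_site_year <- function(raw, config = default_config()) {
  gaps <- run_stage("gap_scan", gap_report(raw))
  if (!gaps$complete) {
    stop_critisus(
      sprintf("[stage gap_scan] Series has %d gap(s); the gap policy admits only complete years.",
              gaps$gap_count),
      "critisus_precondition_error"
    )
  }
  fluct <- run_stage("fluctuations",
                     make_fluctuations(raw, notches = config$notches,
                                       samples_per_day = config$samples_per_day))
  ps <- run_stage("periodogram", periodogram(fluct))
  if (isTRUE(config$spectrum_log_bin)) {
    ps <- run_stage("log_binning",
                    bin_spectrum_log(ps, config$spectrum_bins_per_decade))
  }
  single <- run_stage("single_power_law", suppressWarnings(fit_single_power_law(ps)))
  double <- run_stage("double_power_law", fit_double_power_law(ps))
  comp <- run_stage("model_comparison", compare_models(single, double))
  beta0 <- single$beta
  noise_class <- run_stage("noise_classification", classify_noise(beta0))
  icrit <- run_stage("criticality_index", criticality_index(beta0))
  iscale <- run_stage("scale_invariance_index", scale_invariance_index(comp$dbic))
  ih <- run_stage("health_index", health_index(icrit, iscale))
  im <- run_stage("ordinal_info", info_measures(fluct$value, config$D, config$tau))
  phase <- run_stage(
    "phase_fisher",
    phase_fisher_information(fluct$value, dt = 1 / config$samples_per_day,
                             floor_mult = config$phase_floor_mult,
                             alpha = config$phase_alpha)
  )
  s_index <- run_stage("sustainability_index", sustainability_index(ih, im$H))

  year <- if ("timestamp" %in% names(raw)) {
    as.integer(format(raw$timestamp[1], "%Y", tz = "UTC"))
  } else NA_integer_
  structure(
    tibble(
      site_id = attr(raw, "site_id") %||% NA_character_,
      year = year,
      beta0 = beta0,
      beta1 = double$beta1,
      beta2 = double$beta2,
      crossover = double$crossover_frequency,
      dbic = comp$dbic,
      noise_class = noise_class,
      icrit = icrit,
      iscale = iscale,
      ih = ih,
      H = im$H,
      C = im$C,
      F_ordinal = im$F,
      I_phase = phase$I,
      s_index = s_index,
      n_samples = nrow(raw),
      tie_count = im$tie_count,
      nonpositive_spectrum_points = single$n_dropped,
      config_hash = config_hash(config)
    ),
    class = c("site_year_report", class(tibble()))
  )
}

#' Multi-year Fisher-information trajectory for one site
#'
#' Orders per-year reports into a trajectory of the chosen Fisher measure,
#' the view in which the sustainability hypothesis — stable systems neither
#' gain nor lose Fisher information — is read. When a changepoint year is
#' supplied, per-segment means (years `<=` changepoint vs after) summarise a
#' candidate regime shift.
#'
#' @param reports Data frame of [analyze_site_year()] rows (>= 2, one site).
#' @param changepoint_year Optional year splitting the record into two
#'   regimes.
#' @param measure Column to track: `"F_ordinal"` (default) or `"I_phase"`.
#' @return Tibble (`year`, `F`, `noise_class`) sorted by year, with
#'   attributes `site_id` and, when a changepoint is given, `segment_means`
#'   (tibble: `segment`, `mean_F`, `n_years`).
#' @export
fisher_evolution <- function(reports, changepoint_year = NULL,
                             measure = c("F_ordinal", "I_phase")) {
  measure <- match.arg(measure)
  if (nrow(reports) < 2) {
    stop_critisus("Need >= 2 site-year reports.", "critisus_validation_error")
  }
  sites <- unique(reports$site_id)
  if (length(sites) != 1) {
    stop_critisus("Reports mix sites; trajectories are per-site.",
                  "critisus_validation_error")
  }
  traj <- tibble(
    year = reports$year,
    F = reports[[measure]],
    noise_class = reports$noise_class
  )
  traj <- traj[order(traj$year), ]
  if (anyDuplicated(traj$year)) {
    stop_critisus("Duplicate years in reports.", "critisus_validation_error")
  }
  seg <- NULL
  if (!is.null(changepoint_year)) {
    before <- traj$F[traj$year <= changepoint_year]
    after <- traj$F[traj$year > changepoint_year]
    seg <- tibble(
      segment = c("before", "after"),
      mean_F = c(mean(before), mean(after)),
      n_years = c(length(before), length(after))
    )
  }
  structure(traj, site_id = sites, segment_means = seg,
            class = c("fisher_trajectory", class(traj)))
}
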