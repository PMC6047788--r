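#' Read an AmeriFlux-style half-hourly flux table
#'
#' Expects a CSV with a `TIMESTAMP_START` column in `YYYYMMDDHHMM` form and
#' one column per flux variable, with missing values encoded by a sentinel
#' (default -9999). Timestamps are interpreted as local standard site time
#' (no DST), so the diurnal cycle sits exactly at 1 cycle/day.
#'
#' @param path CSV file path.
#' @param variable Name of the flux column to extract.
#' @param sentinel Missing-value code.
#' @param site_id Site label; defaults to the file name without extension.
#'
#' @return A raw flux series tibble (`timestamp`, `value`, `missing`) with
#'   attributes `site_id`, `variable_name`, `sentinel`.
#' @export
read_flux_table <- function(path, variable = "RECO", sentinel = -9999,
                            site_id = NULL) {
  if (!file.exists(path)) {
    stop_critisus(sprintf("File not found: %s", path), "critisus_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double(),
                                                      TIMESTAMP_START = readr::col_character()),
                        progress = FALSE)
  if (!"TIMESTAMP_START" %in% names(df)) {
    stop_critisus("Column `TIMESTAMP_START` is missing.", "critisus_format_error")
  }
  if (!variable %in% names(df)) {
    stop_critisus(sprintf("Flux column `%s` is missing.", variable),
                  "critisus_format_error")
  }
  ts <- as.POSIXct(df$TIMESTAMP_START, format = "%Y%m%d%H%M", tz = "UTC")
  if (anyNA(ts)) {
    stop_critisus(sprintf("Unparseable timestamp at row %d.", which(is.na(ts))[1]),
                  "critisus_format_error")
  }
  check_half_hourly(ts)
  values <- df[[variable]]
  missing <- !is.na(values) & values == sentinel
  missing[is.na(values)] <- TRUE
  new_raw_flux(
    tibble(timestamp = ts, value = values, missing = missing),
    site_id = site_id %||% sub("\\.[^.]*$", "", basename(path)),
    variable_name = variable, sentinel = sentinel
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_half_hourly <- function(ts) {
  if (length(ts) > 1L) {
    dt <- diff(as.numeric(ts))
    bad <- which(dt != 1800)
    if (length(bad)) {
      stop_critisus(
        sprintf("Timestamps not at 30-min spacing: first offending row %d.",
                bad[1] + 2L),  # file line: header + 1-based offset
        "critisus_format_error"
      )
    }
  }
  invisible(ts)
}

#' Write a flux series in the CSV dialect [read_flux_table()] reads
#'
#' Missing samples are written as the sentinel, enabling lossless round trips
#' of synthetic site-years.
#'
#' @param series A raw flux series.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(series, path) {
  sentinel <- attr(series, "sentinel") %||% -9999
  vals <- series$value
  vals[series$missing] <- sentinel
  out <- tibble(
    TIMESTAMP_START = format(series$timestamp, "%Y%m%d%H%M", tz = "UTC")
  )
  out[[attr(series, "variable_name") %||% "RECO"]] <- vals
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarise gaps in a flux series
#'
#' Scans the missing mask and reports contiguous runs of missing samples.
#' Spectral analysis requires evenly spaced, gap-free input, so any gap makes
#' the series incomplete.
#'
#' @param series A raw flux series.
#' @return One-row tibble: `gap_count`, `complete`, and `gap_spans`
#'   (list-column of `(start, length)` pairs).
#' @export
gap_report <- function(series) {
  r <- rle(series$missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  spans <- Map(c, starts[keep], r$lengths[keep])
  tibble(
    gap_count = length(spans),
    complete = length(spans) == 0L,
    gap_spans = list(spans)
  )
}

#' Split a flux series into calendar years
#'
#' @param series A raw flux series.
#' @return Nested tibble with columns `year` (integer) and `series`
#'   (list-column of raw flux series); concatenating the segments in order
#'   reproduces the input. Years with no samples are absent.
#' @export
segment_by_year <- function(series) {
  yr <- as.integer(format(series$timestamp, "%Y", tz = "UTC"))
  site_id <- attr(series, "site_id")
  varname <- attr(series, "variable_name")
  sentinel <- attr(series, "sentinel")
  years <- sort(unique(yr))
  tibble(
    year = years,
    series = lapply(years, function(y) {
      new_raw_flux(series[yr == y, , drop = FALSE],
                   site_id = site_id, variable_name = varname,
                   sentinel = sentinel)
    })
  )
}

expected_year_length <- function(year, samples_per_day = HALF_HOURLY) {
  days <- if ((year %% 4 == 0 && year %% 100 != 0) || year %% 400 == 0) 366L else 365L
  days * samples_per_day
}

#' Keep only complete, gap-free calendar years
#'
#' Retains segments with zero missing samples and full expected length
#' (17,520 half-hours, or 17,568 in leap years). Gap interpolation is
#' deliberately not offered: spectra and ordinal patterns are computed only
#' on fully observed years.
#'
#' @param segments Output of [segment_by_year()].
#' @return The retained rows of `segments`; idempotent.
#' @export
select_complete_years <- function(segments) {
  keep <- vapply(seq_len(nrow(segments)), function(i) {
    s <- segments$series[[i]]
    expected <- expected_year_length(segments$year[i])
    # leap years either full (17,568) or truncated to 17,520 are accepted
    ok_len <- nrow(s) == expected || (expected == 17568L && nrow(s) == 17520L)
    ok_len && !any(s$missing)
  }, logical(1))
  segments[keep, , drop = FALSE]
}
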