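#' Station-year inclusion thresholds
#'
#' Defaults follow the compliance proxies used for volunteer counting
#' stations: exclude a station-year when more than 60% of calendar days lack
#' a pollen record, or when a run of more than 4 consecutive missing days
#' falls within 10 days of the first "high" pollen day (>= 200 grains/m3).
#'
#' @param max_pct_missing exclusion bound on percent missing days (strict
#'   `>`), percent.
#' @param max_gap_near_high exclusion bound on a missing run near the first
#'   high day (strict `>`), days.
#' @param high_threshold concentration defining a "high" pollen day,
#'   grains/m3.
#' @param high_window_halfwidth half-width of the window around the first
#'   high day, days.
#' @param gt_sparse_floor optional minimum number of non-missing days for a
#'   search site-year (`NA` disables the screen).
#' @return a `quality_thresholds` list.
#' @export
quality_thresholds <- function(max_pct_missing = 60, max_gap_near_high = 4,
                               high_threshold = 200, high_window_halfwidth = 10,
                               gt_sparse_floor = NA) {
  p <- list(max_pct_missing = max_pct_missing,
            max_gap_near_high = max_gap_near_high,
            high_threshold = high_threshold,
            high_window_halfwidth = high_window_halfwidth,
            gt_sparse_floor = gt_sparse_floor)
  check_nonneg(p, c("max_pct_missing", "max_gap_near_high", "high_threshold",
                    "high_window_halfwidth"))
  structure(p, class = "quality_thresholds")
}

#' Percent of missing days in a window
#'
#' @param series a `daily_series`.
#' @param window inclusive day-of-year range; default the series window.
#' @param zero_as_missing treat reported zeros as missing. For search series
#'   this counts censored (unquantified) days as missing, the convention used
#'   for the search-data missingness metric.
#' @return percentage in \[0, 100\].
#' @export
percent_missing <- function(series, window = NULL, zero_as_missing = FALSE) {
  d <- window_days(series, window)
  v <- series$values[d]
  miss <- is.na(v)
  if (zero_as_missing) miss <- miss | (!is.na(v) & v == 0)
  100 * sum(miss) / length(d)
}

#' Longest run of consecutive missing days in a window
#'
#' Runs truncated by the window edges count only their in-window length.
#'
#' @inheritParams percent_missing
#' @return length in days (0 when nothing is missing).
#' @export
longest_gap <- function(series, window = NULL) {
  runs <- missing_runs(series, window)
  if (nrow(runs) == 0) 0L else max(runs$length)
}

#' First day with a high pollen concentration
#'
#' @param series a `daily_series`.
#' @param high_threshold grains/m3 defining a "high" day.
#' @param window inclusive day range; default the series window.
#' @return smallest day-of-year whose observed value is `>= high_threshold`,
#'   or `NA` if the threshold is never reached.
#' @export
first_high_day <- function(series, high_threshold = 200, window = NULL) {
  d <- window_days(series, window)
  v <- series$values[d]
  hit <- which(!is.na(v) & v >= high_threshold)
  if (length(hit) == 0) NA_integer_ else d[hit[1]]
}

#' Apply station-year inclusion criteria
#'
#' A station-year is excluded when (strictly) more than `max_pct_missing`
#' percent of the assessment-window days are missing, when a maximal run of
#' missing days intersecting the interval `first_high_day +/-
#' high_window_halfwidth` is (strictly) longer than `max_gap_near_high`
#' days, or when the analysis window holds no data at all. The near-high rule
#' is skipped (not failed) when no high day exists.
#'
#' @param series a `daily_series` (pollen).
#' @param thresholds a [quality_thresholds()] object.
#' @param window assessment window for the missingness percentage; default
#'   the full calendar year.
#' @param analysis_window window that must contain at least one observation
#'   (default Jan 1 -- Jun 30).
#' @return a `quality_report` list: `pct_missing_days`, `longest_gap_days`,
#'   `first_data_day`, `first_high_day`, `gap_near_first_high_days`,
#'   `included`, `exclusion_reasons`.
#' @export
apply_inclusion <- function(series, thresholds = quality_thresholds(),
                            window = NULL, analysis_window = c(1L, 181L)) {
  stopifnot(inherits(series, "daily_series"),
            inherits(thresholds, "quality_thresholds"))
  nd <- length(series$values)
  if (is.null(window)) window <- c(1L, nd)
  analysis_window <- check_window(analysis_window, nd)
  pct <- percent_missing(series, window)
  gap <- longest_gap(series, window)
  fdd <- first_data_day(series, window)
  fhd <- first_high_day(series, thresholds$high_threshold, window)
  reasons <- character()
  gap_near <- NA_integer_
  if (n_observed(series, analysis_window) == 0) {
    reasons <- c(reasons, "no_data_in_window")
  }
  if (pct > thresholds$max_pct_missing) {
    reasons <- c(reasons, "missingness")
  }
  if (!is.na(fhd)) {
    hw <- thresholds$high_window_halfwidth
    lo <- max(window[1], fhd - hw)
    hi <- min(window[2], fhd + hw)
    runs <- missing_runs(series, window)
    near <- runs[runs$start <= hi & runs$end >= lo, , drop = FALSE]
    gap_near <- if (nrow(near)) max(near$length) else 0L
    if (gap_near > thresholds$max_gap_near_high) {
      reasons <- c(reasons, "gap_near_first_high")
    }
  }
  structure(list(pct_missing_days = pct, longest_gap_days = gap,
                 first_data_day = fdd, first_high_day = fhd,
                 gap_near_first_high_days = gap_near,
                 included = length(reasons) == 0,
                 exclusion_reasons = reasons),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %.1f%% missing, longest gap %d d, %s\n",
              x$pct_missing_days, x$longest_gap_days,
              if (x$included) "included" else
                paste("excluded:", paste(x$exclusion_reasons, collapse = ", "))))
  invisible(x)
}

#' Tabulate quality reports for a set of station-years
#'
#' @param stations list of `station_year` objects.
#' @param thresholds a [quality_thresholds()] object.
#' @param analysis_window window passed to [apply_inclusion()].
#' @return data frame, one row per station-year, with the report fields and a
#'   logical column per exclusion reason.
#' @export
quality_table <- function(stations, thresholds = quality_thresholds(),
                          analysis_window = c(1L, 181L)) {
  rows <- lapply(stations, function(st) {
    q <- apply_inclusion(st$series, thresholds,
                         analysis_window = analysis_window)
    data.frame(site_year_id = st$site_year_id,
               pct_missing_days = q$pct_missing_days,
               longest_gap_days = q$longest_gap_days,
               first_data_day = q$first_data_day,
               first_high_day = q$first_high_day,
               gap_near_first_high_days = q$gap_near_first_high_days,
               included = q$included,
               reason_no_data = "no_data_in_window" %in% q$exclusion_reasons,
               reason_missingness = "missingness" %in% q$exclusion_reasons,
               reason_gap_near_high = "gap_near_first_high" %in% q$exclusion_reasons,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
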