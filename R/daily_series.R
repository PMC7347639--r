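#' Daily series for one calendar year
#'
#' The basic container used throughout the package: one calendar year of
#' dated daily values (pollen concentrations in grains/m3, or adjusted search
#' volumes on the 0--100 scale) with explicit missingness. Values are stored
#' as a numeric vector indexed by day-of-year (1-based, length 365 or 366);
#' `NA` marks a day with no measurement, which is distinct from a reported
#' zero. A series carries an active window (inclusive day-of-year range) that
#' downstream operations respect; the default window is the full year.
#'
#' @param values numeric vector of length `days_in_year(year)`; `NA` = missing.
#' @param year calendar year (integer); determines length and leap handling.
#' @param kind `"pollen"` (grains/m3, any non-negative value) or `"search"`
#'   (adjusted search volume, values in \[0, 100\]).
#' @param window inclusive day-of-year range `c(first, last)`; default full year.
#' @return an object of class `daily_series`.
#' @examples
#' s <- daily_series(c(rep(NA, 50), rep(10, 315)), year = 2015, kind = "pollen")
#' n_observed(s)
#' @export
daily_series <- function(values, year, kind = c("pollen", "search"),
                         window = NULL) {
  kind <- match.arg(kind)
  year <- check_year(year)
  nd <- days_in_year(year)
  values <- as.numeric(values)
  if (length(values) != nd) {
    stop(sprintf("`values` must have length %d for year %d, got %d",
                 nd, year, length(values)), call. = FALSE)
  }
  obs <- values[!is.na(values)]
  if (any(obs < 0)) stop("daily series values must be non-negative", call. = FALSE)
  if (kind == "search" && any(obs > 100)) {
    stop("search volumes must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(window)) window <- c(1L, nd)
  window <- check_window(window, nd)
  structure(list(values = values, year = year, kind = kind, window = window),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %s, year %d, window [%d, %d], %d/%d days observed\n",
              x$kind, x$year, x$window[1], x$window[2],
              n_observed(x), diff(x$window) + 1L))
  invisible(x)
}

#' Number of days in a calendar year
#' @param year calendar year.
#' @return 365 or 366.
#' @export
days_in_year <- function(year) {
  ifelse(is_leap_year(year), 366L, 365L)
}

#' Is a year a leap year?
#' @param year calendar year.
#' @return logical.
#' @export
is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
}

check_year <- function(year) {
  if (length(year) != 1 || !is.finite(year) || year != as.integer(year) ||
      year < 1583 || year > 9999) {
    stop("`year` must be a single calendar year (integer)", call. = FALSE)
  }
  as.integer(year)
}

check_window <- function(window, nd) {
  if (length(window) != 2 || any(!is.finite(window))) {
    stop("`window` must be c(first_day, last_day)", call. = FALSE)
  }
  window <- as.integer(window)
  if (window[1] < 1 || window[2] > nd || window[1] > window[2]) {
    stop(sprintf("window [%d, %d] is empty or outside 1..%d",
                 window[1], window[2], nd), call. = FALSE)
  }
  window
}

#' Day-of-year indices covered by a series window
#' @param series a `daily_series`.
#' @param window optional inclusive day range overriding the series window.
#' @return integer vector of day-of-year indices.
#' @export
window_days <- function(series, window = NULL) {
  stopifnot(inherits(series, "daily_series"))
  if (is.null(window)) window <- series$window
  window <- check_window(window, length(series$values))
  seq.int(window[1], window[2])
}

#' Values of a series over a window
#' @inheritParams window_days
#' @return numeric vector (with `NA` for missing days), named by day-of-year.
#' @export
series_values <- function(series, window = NULL) {
  d <- window_days(series, window)
  stats::setNames(series$values[d], d)
}

#' Count of observed (non-missing) days in the window
#' @inheritParams window_days
#' @export
n_observed <- function(series, window = NULL) {
  sum(!is.na(series$values[window_days(series, window)]))
}

#' Day-of-year of the first observed value
#' @inheritParams window_days
#' @return day-of-year, or `NA` if no data in the window.
#' @export
first_data_day <- function(series, window = NULL) {
  d <- window_days(series, window)
  obs <- d[!is.na(series$values[d])]
  if (length(obs) == 0) NA_integer_ else obs[1]
}

#' Replace a series' values, keeping year/kind/window
#' @keywords internal
set_values <- function(series, values, kind = series$kind) {
  daily_series(values, series$year, kind, series$window)
}

#' Day-of-year numbers of the weekend days of a year
#' @param year calendar year.
#' @return integer vector of day-of-year indices falling on Saturday or Sunday.
#' @export
weekend_days <- function(year) {
  year <- check_year(year)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  which(format(dates, "%u") %in% c("6", "7"))
}

#' Convert day-of-year to an ISO date
#' @param year calendar year.
#' @param doy day-of-year (1-based).
#' @return `Date` vector.
#' @export
doy_to_date <- function(year, doy) {
  as.Date(sprintf("%d-01-01", check_year(year))) + (doy - 1L)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Maximal runs of consecutive missing days among `days` (a contiguous day
# range); returns a data.frame with start/end/length, possibly 0 rows.
missing_runs <- function(series, window = NULL) {
  d <- window_days(series, window)
  miss <- is.na(series$values[d])
  if (!any(miss)) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = d[starts[keep]], end = d[ends[keep]],
             length = r$lengths[keep])
}
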