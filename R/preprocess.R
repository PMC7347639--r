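#' Transform settings for the correlation and onset pathways
#'
#' @param window analysis window. Either an inclusive day-of-year pair, or a
#'   pair of `"MM-DD"` strings resolved per calendar year (the default,
#'   `c("01-01", "06-30")`, is the early pollen season: 181 days, 182 in leap
#'   years).
#' @param normalize_max target maximum for per-year normalisation of pollen
#'   concentrations (puts them on the same 0--100 scale as search volumes).
#' @param log_offset additive constant used in `log(value + offset)`; must be
#'   > 0 because both sources contain zeros.
#' @param lowess_light_bw LOWESS bandwidth (fraction of observed points per
#'   local neighbourhood) for light smoothing before rank correlation.
#' @param lowess_heavy_bw heavy-smoothing bandwidth used as the baseline in
#'   the peak signal-to-noise statistic.
#' @param lowess_iter robustness iterations for the smoother (0 = plain
#'   tricube local-linear fits).
#' @return a `transform_config` list.
#' @export
transform_config <- function(window = c("01-01", "06-30"), normalize_max = 100,
                             log_offset = 1, lowess_light_bw = 0.1,
                             lowess_heavy_bw = 0.8, lowess_iter = 0L) {
  for (bw in c(lowess_light_bw, lowess_heavy_bw)) {
    if (bw <= 0 || bw > 1) stop("bandwidths must lie in (0, 1]", call. = FALSE)
  }
  if (log_offset <= 0) stop("log_offset must be > 0", call. = FALSE)
  structure(list(window = window, normalize_max = normalize_max,
                 log_offset = log_offset, lowess_light_bw = lowess_light_bw,
                 lowess_heavy_bw = lowess_heavy_bw,
                 lowess_iter = as.integer(lowess_iter)),
            class = "transform_config")
}

#' Resolve a window specification for a calendar year
#'
#' @param window day-of-year pair, or `"MM-DD"` string pair.
#' @param year calendar year (used for `"MM-DD"` windows).
#' @return integer day-of-year pair.
#' @export
resolve_window <- function(window, year) {
  if (is.character(window)) {
    d <- as.Date(sprintf("%d-%s", year, window))
    if (anyNA(d)) stop("window strings must be 'MM-DD'", call. = FALSE)
    window <- as.integer(format(d, "%j"))
  }
  check_window(window, days_in_year(year))
}

# Internal constructor that skips range validation: transformed values (log
# scale, smoother overshoot) may leave the raw value range of the kind.
transformed_series <- function(template, values) {
  structure(list(values = values, year = template$year, kind = template$kind,
                 window = template$window),
            class = "daily_series")
}

#' Restrict a series to a day window
#'
#' Values outside the window are dropped (set missing) and the series' active
#' window is narrowed; missingness inside is preserved.
#'
#' @param series a `daily_series`.
#' @param window day-of-year pair or `"MM-DD"` pair.
#' @return a `daily_series` with the narrowed window.
#' @export
restrict_window <- function(series, window) {
  stopifnot(inherits(series, "daily_series"))
  window <- resolve_window(window, series$year)
  v <- rep(NA_real_, length(series$values))
  d <- seq.int(window[1], window[2])
  v[d] <- series$values[d]
  out <- transformed_series(series, v)
  out$window <- window
  out
}

#' Normalise a series to a target maximum
#'
#' Every observed value is scaled by `target / max(observed values)` so the
#' in-window maximum becomes exactly `target`.
#'
#' @param series a `daily_series` with at least one positive observed value.
#' @param target target maximum (default 100).
#' @return the rescaled series.
#' @export
normalize_to_max <- function(series, target = 100) {
  v <- series$values[window_days(series)]
  mx <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) stop("degenerate series: no positive values",
                                      call. = FALSE)
  out <- series$values * (target / mx)
  transformed_series(series, out)
}

#' Log-transform a series
#'
#' Observed values map to `log(value + offset)`; missing days stay missing.
#'
#' @param series a `daily_series`.
#' @param offset positive additive constant (both data sources contain
#'   legitimate zeros).
#' @return the transformed series.
#' @export
log_transform <- function(series, offset = 1) {
  if (offset <= 0) stop("offset must be > 0", call. = FALSE)
  transformed_series(series, log(series$values + offset))
}

#' LOWESS smoothing of a daily series
#'
#' Classical locally weighted scatterplot smoothing on the (day, value) pairs
#' of the observed days: for each observed day, the nearest
#' `ceiling(bandwidth * n)` observed days by day distance form the local
#' neighbourhood, and a tricube-weighted linear regression fitted on them is
#' evaluated at that day. The bandwidth is the fraction of observed points per
#' neighbourhood (lower = less smoothing). Missing days remain missing.
#' Optional robustness iterations reweight by the bisquare of scaled
#' residuals.
#'
#' @param series a `daily_series` with at least 5 observed days in window.
#' @param bandwidth fraction in (0, 1].
#' @param iter number of robustness iterations (default 0, plain fits).
#' @return the smoothed series (fitted values at observed days).
#' @export
lowess_smooth <- function(series, bandwidth, iter = 0L) {
  stopifnot(inherits(series, "daily_series"))
  if (bandwidth <= 0 || bandwidth > 1) {
    stop("bandwidth must lie in (0, 1]", call. = FALSE)
  }
  d <- window_days(series)
  obs <- d[!is.na(series$values[d])]
  if (length(obs) < 5) stop("too few points: LOWESS needs >= 5 observed days",
                            call. = FALSE)
  fit <- lowess_fit(obs, series$values[obs], bandwidth, iter)
  v <- rep(NA_real_, length(series$values))
  v[obs] <- fit
  transformed_series(series, v)
}

# Tricube local-linear LOWESS at the observed x themselves. x must be sorted
# unique numerics (day-of-year here). Neighbourhood = nearest q = ceiling(f*n)
# points (ties by distance all included via the q-th-distance cutoff).
lowess_fit <- function(x, y, f, iter = 0L) {
  n <- length(x)
  q <- min(n, max(2L, as.integer(ceiling(f * n))))
  rw <- rep(1, n)
  fitted <- numeric(n)
  for (it in seq_len(iter + 1L)) {
    for (i in seq_len(n)) {
      dist <- abs(x - x[i])
      h <- sort(dist, partial = q)[q]
      w <- numeric(n)
      inside <- dist < h
      w[inside] <- (1 - (dist[inside] / h)^3)^3
      w[dist == 0] <- 1
      w <- w * rw
      sw <- sum(w)
      xb <- sum(w * x) / sw
      yb <- sum(w * y) / sw
      sxx <- sum(w * (x - xb)^2)
      fitted[i] <- if (sxx > 0) {
        yb + sum(w * (x - xb) * (y - yb)) / sxx * (x[i] - xb)
      } else yb
    }
    if (it <= iter) {
      res <- y - fitted
      s <- stats::median(abs(res))
      if (s == 0) break
      u <- pmin(abs(res) / (6 * s), 1)
      rw <- (1 - u^2)^2
    }
  }
  fitted
}

#' Apply the standard transform stack to a series
#'
#' The correlation pathway restricts to the analysis window, normalises
#' pollen concentrations to the search-volume scale, log-transforms, and
#' lightly smooths. The `variant` argument selects the data version used in
#' onset comparisons.
#'
#' @param series a `daily_series`.
#' @param config a [transform_config()].
#' @param variant `"raw"` (window only), `"smoothed"` (window, optional
#'   normalise, light LOWESS), or `"log_smoothed"` (window, optional
#'   normalise, log, light LOWESS).
#' @param normalize whether to max-normalise before smoothing (used for
#'   pollen; search volumes are already on 0--100).
#' @return the transformed `daily_series`.
#' @export
transform_series <- function(series, config = transform_config(),
                             variant = c("log_smoothed", "smoothed", "raw"),
                             normalize = series$kind == "pollen") {
  variant <- match.arg(variant)
  s <- restrict_window(series, config$window)
  if (variant == "raw") return(s)
  if (normalize) s <- normalize_to_max(s, config$normalize_max)
  if (variant == "log_smoothed") s <- log_transform(s, config$log_offset)
  lowess_smooth(s, config$lowess_light_bw, config$lowess_iter)
}
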