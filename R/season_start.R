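#' Pollen-season start definition
#'
#' Three families of onset rules are supported: the day the cumulative sum
#' reaches a fraction of the annual total (`"cumulative_fraction"`, fractions
#' 0.05 or 0.025 in common use), the first day of a run of consecutive days
#' with recorded pollen (`"consecutive_days"`, typically 4), and the first
#' day an absolute concentration threshold is met
#' (`"absolute_threshold"`, typically 200 grains/m3).
#'
#' @param method one of `"cumulative_fraction"`, `"consecutive_days"`,
#'   `"absolute_threshold"`.
#' @param fraction cumulative fraction in (0, 1) (cumulative method only).
#' @param run_length run length in days (consecutive method only).
#' @param threshold grains/m3 (absolute method only).
#' @param comparator `">="` (default; matches the "high day" definition) or
#'   `">"` for the absolute rule.
#' @param variant data version the estimator runs on: `"raw"`, `"smoothed"`,
#'   or `"log_smoothed"`.
#' @return a `start_definition` list.
#' @export
start_definition <- function(method = c("cumulative_fraction",
                                        "consecutive_days",
                                        "absolute_threshold"),
                             fraction = 0.05, run_length = 4L, threshold = 200,
                             comparator = c(">=", ">"),
                             variant = c("raw", "smoothed", "log_smoothed")) {
  method <- match.arg(method)
  comparator <- match.arg(comparator)
  variant <- match.arg(variant)
  if (method == "cumulative_fraction" && (fraction <= 0 || fraction >= 1)) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (method == "consecutive_days" && run_length < 1) {
    stop("run_length must be >= 1", call. = FALSE)
  }
  if (method == "absolute_threshold" && threshold < 0) {
    stop("threshold must be >= 0", call. = FALSE)
  }
  structure(list(method = method, fraction = fraction,
                 run_length = as.integer(run_length), threshold = threshold,
                 comparator = comparator, variant = variant),
            class = "start_definition")
}

season_start_result <- function(start_day, basis_total = NA_real_,
                                flag = NA_character_) {
  list(start_day = start_day, basis_total = basis_total, flag = flag)
}

#' Season start by cumulative fraction of the annual total
#'
#' The start is the smallest day whose running cumulative sum (missing days
#' contribute 0; no imputation) reaches `fraction` times the total over
#' `total_window`.
#'
#' @param series a `daily_series`.
#' @param fraction fraction of the total, in (0, 1).
#' @param total_window window over which the "annual total" is accumulated;
#'   default the full calendar year. For search-derived starts use the
#'   analysis window, since search data are only collected for the early
#'   season.
#' @param scan_window window scanned for the start day; default
#'   `total_window`.
#' @return list `start_day` (day-of-year or `NA`), `basis_total`, `flag`
#'   (`"zero_total"` when the total is 0).
#' @export
start_cumulative <- function(series, fraction = 0.05, total_window = NULL,
                             scan_window = NULL) {
  stopifnot(inherits(series, "daily_series"))
  if (is.null(total_window)) total_window <- c(1L, length(series$values))
  if (is.null(scan_window)) scan_window <- total_window
  td <- window_days(series, resolve_window(total_window, series$year))
  v <- series$values[td]
  v[is.na(v)] <- 0
  total <- sum(v)
  if (total <= 0) return(season_start_result(NA_integer_, total, "zero_total"))
  cum <- cumsum(v)
  sd0 <- resolve_window(scan_window, series$year)
  hit <- which(cum >= fraction * total & td >= sd0[1] & td <= sd0[2])
  day <- if (length(hit)) td[hit[1]] else NA_integer_
  season_start_result(day, total)
}

#' Season start by a run of consecutive days with recorded pollen
#'
#' @param series a `daily_series`.
#' @param run_length required number of consecutive observed days with
#'   value > 0.
#' @param window day range scanned; default the series window.
#' @return list with `start_day` = first day of the earliest qualifying run,
#'   or `NA` when no run exists.
#' @export
start_consecutive <- function(series, run_length = 4L, window = NULL) {
  d <- window_days(series, window)
  pos <- !is.na(series$values[d]) & series$values[d] > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= run_length)
  day <- if (length(ok)) d[starts[ok[1]]] else NA_integer_
  season_start_result(day)
}

#' Season start by an absolute concentration threshold
#'
#' First observed day whose value meets the threshold (`>=` by default,
#' matching the "high pollen day" definition; `>` available).
#'
#' @param series a `daily_series`.
#' @param threshold grains/m3.
#' @param comparator `">="` or `">"`.
#' @param window day range scanned; default the series window.
#' @return list with `start_day` or `NA`.
#' @export
start_absolute <- function(series, threshold = 200, comparator = ">=",
                           window = NULL) {
  d <- window_days(series, window)
  v <- series$values[d]
  hit <- if (comparator == ">=") which(!is.na(v) & v >= threshold)
         else which(!is.na(v) & v > threshold)
  day <- if (length(hit)) d[hit[1]] else NA_integer_
  season_start_result(day)
}

#' Season start of a series under a named definition
#'
#' Applies the definition's transform variant and onset rule. For
#' search-kind series the cumulative total is accumulated over the analysis
#' window (search data exist only for the early season); for pollen the
#' total spans the full calendar year.
#'
#' @param series a `daily_series`.
#' @param definition a [start_definition()].
#' @param config a [transform_config()] (supplies the analysis window and
#'   smoothing settings for non-raw variants).
#' @return list `start_day`, `basis_total`, `flag`.
#' @export
season_start <- function(series, definition = start_definition(),
                         config = transform_config()) {
  stopifnot(inherits(definition, "start_definition"))
  is_search <- series$kind == "search"
  s <- if (definition$variant == "raw") series else {
    transform_series(series, config, definition$variant,
                     normalize = series$kind == "pollen")
  }
  switch(definition$method,
    cumulative_fraction = {
      tw <- if (is_search || definition$variant != "raw") {
        resolve_window(config$window, series$year)
      } else c(1L, length(series$values))
      start_cumulative(s, definition$fraction, total_window = tw)
    },
    consecutive_days = start_consecutive(s, definition$run_length),
    absolute_threshold = start_absolute(s, definition$threshold,
                                        definition$comparator))
}

#' Search-derived season start
#'
#' Applies the cumulative-fraction rule (default 5%) to the chosen variant of
#' the search series over the analysis window, using the window sum as the
#' annual total. Censored zeros contribute 0 to the accumulation.
#'
#' @param search a `daily_series` of kind `"search"`.
#' @param definition a [start_definition()] (cumulative by default).
#' @param config a [transform_config()].
#' @return list `start_day`, `basis_total`, `flag` (`"zero_total"` for an
#'   all-zero search year).
#' @export
gt_season_start <- function(search, definition = start_definition(),
                            config = transform_config()) {
  season_start(search, definition, config)
}

#' Start-date discrepancy analysis over a matched panel
#'
#' For every matched site-year and every data variant, computes the
#' search-derived and pollen-derived season starts (cumulative rule) and
#' their difference `delta = gt_start - nab_start` (negative = search starts
#' earlier). Inclusion tiers are applied cumulatively: (a) all site-years
#' passing the quality screen; (b) additionally the pollen record begins
#' within the first month of the year (`first_data_day <= 31`); (c)
#' additionally the search series has under 20% missing (zero or absent)
#' days. A previous-year baseline (current pollen start minus prior-year
#' pollen start at the same station) is reported where the prior year
#' exists.
#'
#' @param panel a `pollen_panel` or list with `stations`/`regions`.
#' @param matches optional match table from [match_station_to_region()].
#' @param fraction cumulative fraction for both sources.
#' @param variants data variants to evaluate.
#' @param config a [transform_config()].
#' @param thresholds a [quality_thresholds()] applied before tiering.
#' @param gt_missing_cap tier (c) cap on percent missing search days.
#' @return list `records` (data frame: site-year, variant, starts, delta,
#'   tier flags, prev-year delta) and `summary` (data frame of per-tier,
#'   per-variant n / median / IQR of delta).
#' @export
discrepancy_analysis <- function(panel, matches = NULL, fraction = 0.05,
                                 variants = c("raw", "smoothed", "log_smoothed"),
                                 config = transform_config(),
                                 thresholds = quality_thresholds(),
                                 gt_missing_cap = 20) {
  pairs <- panel_pairs(panel, matches)
  nab_starts <- list()  # station_id -> year -> start day (raw variant)
  rows <- list()
  for (pr in pairs) {
    st <- pr$station; rg <- pr$region
    qc <- apply_inclusion(st$series, thresholds,
                          analysis_window = resolve_window(config$window,
                                                           st$series$year))
    if (!qc$included) next
    gt_missing <- percent_missing(restrict_window(rg$averaged, config$window),
                                  zero_as_missing = TRUE)
    for (variant in variants) {
      defn <- start_definition("cumulative_fraction", fraction = fraction,
                               variant = variant)
      nab <- tryCatch(season_start(st$series, defn, config),
                      error = function(e) season_start_result(NA_integer_))
      gt <- tryCatch(gt_season_start(rg$averaged, defn, config),
                     error = function(e) season_start_result(NA_integer_))
      if (variant == "raw") {
        key <- st$station_id
        nab_starts[[key]] <- c(nab_starts[[key]],
                               stats::setNames(nab$start_day,
                                               as.character(st$series$year)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site_year_id = st$site_year_id, station_id = st$station_id,
        year = st$series$year, variant = variant,
        gt_start = gt$start_day, nab_start = nab$start_day,
        delta_days = gt$start_day - nab$start_day,
        first_data_day = qc$first_data_day, pct_gt_missing = gt_missing,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(list(records = data.frame(), summary = data.frame()))
  }
  rec <- do.call(rbind, rows)
  rec$tier_all <- TRUE
  rec$tier_early_nab <- !is.na(rec$first_data_day) & rec$first_data_day <= 31
  rec$tier_low_gt_missing <- rec$tier_early_nab &
    rec$pct_gt_missing < gt_missing_cap
  rec$prev_year_nab_start <- mapply(function(sid, yr) {
    s <- nab_starts[[sid]]
    if (!is.null(s) && as.character(yr - 1) %in% names(s)) {
      s[[as.character(yr - 1)]]
    } else NA_integer_
  }, rec$station_id, rec$year)
  rec$prev_year_delta <- rec$nab_start - rec$prev_year_nab_start
  tiers <- c(all = "tier_all", early_nab_data = "tier_early_nab",
             low_gt_missing = "tier_low_gt_missing")
  summ <- do.call(rbind, lapply(names(tiers), function(tn) {
    do.call(rbind, lapply(variants, function(vv) {
      dd <- rec$delta_days[rec[[tiers[[tn]]]] & rec$variant == vv]
      dd <- dd[!is.na(dd)]
      data.frame(tier = tn, variant = vv, n = length(dd),
                 median_delta = if (length(dd)) stats::median(dd) else NA_real_,
                 iqr_lo = if (length(dd)) stats::quantile(dd, 0.25, names = FALSE)
                          else NA_real_,
                 iqr_hi = if (length(dd)) stats::quantile(dd, 0.75, names = FALSE)
                          else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(records = rec, summary = summ)
}
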