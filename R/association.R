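#' Spearman rank correlation between two daily series
#'
#' Computed over the pairwise-complete day set: days where both series are
#' observed, optionally excluding a supplied set of censored days. Ties get
#' average ranks; rho is the Pearson correlation of the rank vectors.
#'
#' @param x,y `daily_series` objects sharing a year.
#' @param window day range; default the intersection of the two windows.
#' @param exclude_days optional day-of-year vector removed from the pairwise
#'   set (e.g. days where the raw search volume was zero-censored).
#' @param min_days minimum joint days required to report rho (default 3).
#' @return list `rho`, `n_days`, `ok` (`FALSE` with `rho = NA` when fewer
#'   than `min_days` joint days exist or a series is constant).
#' @export
spearman_rho <- function(x, y, window = NULL, exclude_days = NULL,
                         min_days = 3L) {
  stopifnot(inherits(x, "daily_series"), inherits(y, "daily_series"))
  if (x$year != y$year) stop("series must share a year", call. = FALSE)
  if (is.null(window)) {
    window <- c(max(x$window[1], y$window[1]), min(x$window[2], y$window[2]))
  }
  d <- window_days(x, window)
  joint <- d[!is.na(x$values[d]) & !is.na(y$values[d])]
  if (!is.null(exclude_days)) joint <- setdiff(joint, exclude_days)
  n <- length(joint)
  if (n < min_days) {
    return(list(rho = NA_real_, n_days = n, ok = FALSE))
  }
  xv <- x$values[joint]
  yv <- y$values[joint]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    return(list(rho = NA_real_, n_days = n, ok = FALSE))
  }
  list(rho = stats::cor(xv, yv, method = "spearman"), n_days = n, ok = TRUE)
}

#' Peak signal-to-noise statistic of a search series
#'
#' The mean absolute difference between the raw (untransformed) daily values
#' and a heavily smoothed LOWESS baseline (default bandwidth 0.8): series
#' with a sharp seasonal peak deviate strongly from their smoothed baseline,
#' flat noisy series do not. Units are those of the input (adjusted search
#' volume).
#'
#' @param search_raw a `daily_series` (raw search volumes, window applied).
#' @param heavy_bw heavy-smoothing bandwidth.
#' @param iter robustness iterations for the smoother.
#' @return non-negative statistic.
#' @export
peak_snr <- function(search_raw, heavy_bw = 0.8, iter = 0L) {
  smooth <- lowess_smooth(search_raw, heavy_bw, iter)
  d <- window_days(search_raw)
  obs <- d[!is.na(search_raw$values[d])]
  mean(abs(search_raw$values[obs] - smooth$values[obs]))
}

#' Per-site-year association analysis over a matched panel
#'
#' For each matched station/region pair: restrict both series to the analysis
#' window; compute the search-data quality covariates (percent days missing,
#' percent days zero, peak signal-to-noise of the raw averaged search
#' series); transform both series (pollen: normalise, log, light LOWESS;
#' search: log, light LOWESS); and compute Spearman's rho over jointly
#' observed days, excluding zero-censored search days unless
#' `keep_censored_zeros`.
#'
#' @param panel a `pollen_panel`, or a list with `stations` and `regions`.
#' @param matches match table from [match_station_to_region()]; by default
#'   pairs are matched by position when the panel is synthetic.
#' @param config a [transform_config()].
#' @param keep_censored_zeros retain zero search days in the correlation set
#'   (sensitivity analysis; default drops them, treating unquantified
#'   volumes as missing).
#' @return data frame with one row per pair: `site_year_id`, `rho`, `n_days`,
#'   `pct_gt_missing`, `pct_gt_zero_days`, `peak_snr`, `pct_nab_missing`,
#'   `rho_raw` (rank correlation of the untransformed windowed series, for
#'   comparison), `tv_homes`.
#' @export
association_analysis <- function(panel, matches = NULL,
                                 config = transform_config(),
                                 keep_censored_zeros = FALSE) {
  pairs <- panel_pairs(panel, matches)
  rows <- lapply(pairs, function(pr) {
    st <- pr$station; rg <- pr$region
    search_raw <- restrict_window(rg$averaged, config$window)
    pollen_raw <- restrict_window(st$series, config$window)
    d <- window_days(search_raw)
    zero_days <- d[!is.na(search_raw$values[d]) & search_raw$values[d] == 0]
    pct_zero <- 100 * length(zero_days) / length(d)
    pct_gt_missing <- percent_missing(search_raw, zero_as_missing = TRUE)
    pct_nab_missing <- percent_missing(pollen_raw)
    snr <- tryCatch(peak_snr(search_raw, config$lowess_heavy_bw, config$lowess_iter),
                    error = function(e) NA_real_)
    excl <- if (keep_censored_zeros) NULL else zero_days
    res <- tryCatch({
      ps <- transform_series(st$series, config, "log_smoothed", normalize = TRUE)
      gs_in <- if (keep_censored_zeros) rg$averaged else {
        v <- rg$averaged$values
        v[zero_days] <- NA_real_
        transformed_series(rg$averaged, v)
      }
      gs <- transform_series(gs_in, config, "log_smoothed", normalize = FALSE)
      spearman_rho(gs, ps, exclude_days = excl)
    }, error = function(e) list(rho = NA_real_, n_days = 0L, ok = FALSE))
    raw <- spearman_rho(search_raw, pollen_raw, exclude_days = excl)
    data.frame(site_year_id = st$site_year_id, dma_id = rg$dma_id,
               rho = res$rho, n_days = res$n_days,
               pct_gt_missing = pct_gt_missing, pct_gt_zero_days = pct_zero,
               peak_snr = snr, pct_nab_missing = pct_nab_missing,
               rho_raw = raw$rho, tv_homes = rg$tv_homes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Resolve a panel + optional match table into station/region pairs.
panel_pairs <- function(panel, matches = NULL) {
  stations <- panel$stations
  regions <- panel$regions
  if (is.null(matches)) {
    if (length(stations) != length(regions)) {
      stop("without a match table, stations and regions must pair by position",
           call. = FALSE)
    }
    idx <- data.frame(station_idx = seq_along(stations),
                      region_idx = seq_along(regions))
  } else {
    idx <- matches$matches[, c("station_idx", "region_idx")]
  }
  lapply(seq_len(nrow(idx)), function(k) {
    list(station = stations[[idx$station_idx[k]]],
         region = regions[[idx$region_idx[k]]])
  })
}

#' Quartile stratification of association results
#'
#' Cutoffs are the 25th/50th/75th percentiles of the chosen covariate
#' (linear-interpolation percentiles, `quantile` type 7); a site-year with
#' covariate value `<= c25` falls in Q1, `<= c50` in Q2, `<= c75` in Q3,
#' else Q4. Per-quartile medians and IQRs of rho are reported.
#'
#' @param results data frame from [association_analysis()] (rows with `NA`
#'   covariate are dropped).
#' @param by covariate column: `"pct_gt_missing"`, `"pct_gt_zero_days"` or
#'   `"peak_snr"`.
#' @return list `cutoffs` (length 3), `assignments` (input rows plus a
#'   `quartile` column), `summary` (per-quartile n, median rho, IQR bounds).
#' @export
quartile_stratify <- function(results, by = c("pct_gt_missing",
                                              "pct_gt_zero_days", "peak_snr")) {
  by <- match.arg(by)
  res <- results[!is.na(results[[by]]), , drop = FALSE]
  if (nrow(res) < 4) stop("need at least 4 site-years to form quartiles",
                          call. = FALSE)
  x <- res[[by]]
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(x)) == 1) {
    warning("degenerate cutoffs: covariate constant, all site-years in Q1",
            call. = FALSE)
  }
  q <- ifelse(x <= cuts[1], 1L, ifelse(x <= cuts[2], 2L,
                                       ifelse(x <= cuts[3], 3L, 4L)))
  res$quartile <- q
  summ <- do.call(rbind, lapply(1:4, function(k) {
    rho <- res$rho[res$quartile == k & !is.na(res$rho)]
    data.frame(quartile = k, n = sum(res$quartile == k),
               median_rho = if (length(rho)) stats::median(rho) else NA_real_,
               iqr_lo = if (length(rho)) stats::quantile(rho, 0.25, names = FALSE)
                        else NA_real_,
               iqr_hi = if (length(rho)) stats::quantile(rho, 0.75, names = FALSE)
                        else NA_real_)
  }))
  list(cutoffs = cuts, assignments = res, summary = summ, by = by)
}

#' Compare rho between two groups of site-years
#'
#' Two-sample Student's t-test (pooled variance by default, Welch by flag),
#' plus the per-group medians and IQRs used in reporting.
#'
#' @param a,b numeric vectors (e.g. rho values of two quartiles).
#' @param labels group labels.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return list with `statistic`, `p_value`, `df`, and per-group
#'   median/IQR summaries.
#' @export
compare_groups <- function(a, b, labels = c("A", "B"), var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  tt <- stats::t.test(a, b, var.equal = var_equal)
  summarise <- function(v) {
    c(n = length(v), median = stats::median(v),
      iqr_lo = stats::quantile(v, 0.25, names = FALSE),
      iqr_hi = stats::quantile(v, 0.75, names = FALSE))
  }
  list(group_a = labels[1], group_b = labels[2],
       statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       summary_a = summarise(a), summary_b = summarise(b))
}

#' Univariate screen of a site covariate against a metric
#'
#' Ordinary least-squares fit of `y ~ x` (optionally on `log(x)`), with
#' Pearson's r, R-squared, and the normal-theory 95% confidence interval of
#' the slope — the screening regression used for temperature, precipitation
#' and TV-homes covariates.
#'
#' @param x covariate values.
#' @param y response values.
#' @param log_x regress on `log(x)` (e.g. TV-homes).
#' @param conf_level confidence level for the slope interval.
#' @return list `pearson_r`, `slope`, `intercept`, `r_squared`, `ci_lo`,
#'   `ci_hi`, `p_value`, `n`.
#' @export
screen_covariate <- function(x, y, log_x = FALSE, conf_level = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (log_x) x <- log(x)
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = conf_level)
  sm <- summary(fit)
  list(pearson_r = stats::cor(x, y), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r_squared = sm$r.squared,
       ci_lo = ci[1], ci_hi = ci[2],
       p_value = sm$coefficients["x", "Pr(>|t|)"], n = length(x))
}
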