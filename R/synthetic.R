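#' Parameters of the synthetic annual pollen model
#'
#' The generator emulates the bimodal seasonality typical of U.S. total
#' pollen: one larger peak early in the year (tree pollen) and one smaller
#' peak later (grass/weed). Each peak is a Gaussian bump in day-of-year with
#' an amplitude in grains/m3; daily values are the deterministic seasonal
#' mean multiplied by lognormal noise with unit mean and coefficient of
#' variation `noise_cv`, so the expected value on day d is
#' `baseline + sum_i amplitude_i * exp(-(d - peak_i_day)^2 / (2 * width_i^2))`.
#'
#' @param peak1_day day-of-year of the dominant early-season peak.
#' @param peak1_width_days Gaussian width (days) of the early peak, > 0.
#' @param peak1_amplitude peak height, grains/m3.
#' @param peak2_day,peak2_width_days,peak2_amplitude same for the smaller
#'   late-season peak; `peak2_amplitude` must be < `peak1_amplitude`.
#' @param noise_cv coefficient of variation of multiplicative lognormal daily
#'   noise, >= 0 (0 = noiseless).
#' @param baseline off-season floor, grains/m3, >= 0.
#' @return a `pollen_model_params` list.
#' @export
pollen_model_params <- function(peak1_day = 100, peak1_width_days = 15,
                                peak1_amplitude = 1000,
                                peak2_day = 245, peak2_width_days = 25,
                                peak2_amplitude = 250,
                                noise_cv = 0.4, baseline = 2) {
  p <- list(peak1_day = peak1_day, peak1_width_days = peak1_width_days,
            peak1_amplitude = peak1_amplitude, peak2_day = peak2_day,
            peak2_width_days = peak2_width_days,
            peak2_amplitude = peak2_amplitude,
            noise_cv = noise_cv, baseline = baseline)
  for (f in names(p)) {
    if (length(p[[f]]) != 1 || !is.finite(p[[f]])) {
      stop(sprintf("field `%s` must be a single finite number", f), call. = FALSE)
    }
  }
  check_nonneg(p, c("noise_cv", "baseline", "peak1_amplitude", "peak2_amplitude"))
  check_positive(p, c("peak1_width_days", "peak2_width_days"))
  for (f in c("peak1_day", "peak2_day")) {
    if (p[[f]] < 1 || p[[f]] > 366) {
      stop(sprintf("field `%s` must lie in 1..366", f), call. = FALSE)
    }
  }
  if (p$peak1_amplitude <= p$peak2_amplitude) {
    stop("field `peak1_amplitude` must exceed `peak2_amplitude` (dominant early peak)",
         call. = FALSE)
  }
  structure(p, class = "pollen_model_params")
}

#' Parameters of the synthetic search-volume model
#'
#' Search volumes are modelled as a lagged monotone (power-law) response to
#' pollen plus a baseline search rate, with multiplicative daily noise and
#' additional per-download (replicate) sampling noise. The latent volume on
#' day d is `noise * (baseline_rate + response_scale * pollen(d - lag)^response_exponent)`.
#' Latent values below `censor_threshold` are reported as 0 *before*
#' rescaling, emulating the suppression of low absolute search volumes; each
#' replicate is then independently rescaled so its maximum reported value is
#' 100 and rounded (half-up) to integers.
#'
#' @param lag_days integer lag of searches relative to pollen; negative means
#'   searches precede pollen.
#' @param response_exponent power-law coupling exponent, > 0.
#' @param response_scale multiplicative coupling constant, > 0.
#' @param baseline_rate expected off-season search level before rescaling, >= 0.
#' @param noise_cv coefficient of variation of daily search noise, >= 0.
#' @param censor_threshold pre-rescaling latent volume below which the
#'   reported value is 0, >= 0.
#' @param n_replicates number of simulated downloads, >= 1.
#' @param replicate_noise_cv coefficient of variation of inter-download
#'   sampling noise, >= 0.
#' @return a `search_model_params` list.
#' @export
search_model_params <- function(lag_days = 0L, response_exponent = 1,
                                response_scale = 1, baseline_rate = 20,
                                noise_cv = 0.3, censor_threshold = 0,
                                n_replicates = 10L, replicate_noise_cv = 0.15) {
  p <- list(lag_days = lag_days, response_exponent = response_exponent,
            response_scale = response_scale, baseline_rate = baseline_rate,
            noise_cv = noise_cv, censor_threshold = censor_threshold,
            n_replicates = n_replicates, replicate_noise_cv = replicate_noise_cv)
  for (f in names(p)) {
    if (length(p[[f]]) != 1 || !is.finite(p[[f]])) {
      stop(sprintf("field `%s` must be a single finite number", f), call. = FALSE)
    }
  }
  check_positive(p, c("response_exponent", "response_scale"))
  check_nonneg(p, c("baseline_rate", "noise_cv", "censor_threshold",
                    "replicate_noise_cv"))
  if (p$n_replicates < 1 || p$n_replicates != as.integer(p$n_replicates)) {
    stop("field `n_replicates` must be an integer >= 1", call. = FALSE)
  }
  p$lag_days <- as.integer(p$lag_days)
  p$n_replicates <- as.integer(p$n_replicates)
  structure(p, class = "search_model_params")
}

#' Parameters of station-style missingness
#'
#' Emulates the missingness pattern of volunteer pollen-counting stations:
#' unmeasured weekends, gaps at the start and end of the year, and random
#' mid-year gaps of geometric-like length.
#'
#' @param weekend_missing_prob probability in \[0,1\] that a weekend day is
#'   unmeasured.
#' @param edge_gap_days integer `c(start, end)`: days unmeasured at the year
#'   boundaries.
#' @param random_gap_rate expected number of random gaps per year (Poisson).
#' @param random_gap_length_mean mean random-gap length in days, >= 1.
#' @return a `missingness_params` list.
#' @export
missingness_params <- function(weekend_missing_prob = 0.6,
                               edge_gap_days = c(0L, 0L),
                               random_gap_rate = 3,
                               random_gap_length_mean = 3) {
  if (length(edge_gap_days) != 2 || any(edge_gap_days < 0)) {
    stop("field `edge_gap_days` must be two counts >= 0", call. = FALSE)
  }
  p <- list(weekend_missing_prob = weekend_missing_prob,
            edge_gap_days = as.integer(edge_gap_days),
            random_gap_rate = random_gap_rate,
            random_gap_length_mean = random_gap_length_mean)
  if (p$weekend_missing_prob < 0 || p$weekend_missing_prob > 1) {
    stop("field `weekend_missing_prob` must lie in [0, 1]", call. = FALSE)
  }
  check_nonneg(p, "random_gap_rate")
  if (p$random_gap_length_mean < 1) {
    stop("field `random_gap_length_mean` must be >= 1", call. = FALSE)
  }
  structure(p, class = "missingness_params")
}

#' Specification of a synthetic site-year panel
#'
#' @param n_site_years number of coupled station/region pairs to generate.
#' @param year calendar year (controls weekday layout and leap handling).
#' @param seed integer random seed; a fixed seed makes the panel bit-identical
#'   across runs.
#' @param pollen a [pollen_model_params()] object (per-site jitter is applied
#'   around it, see `jitter`).
#' @param search a [search_model_params()] object.
#' @param missingness a [missingness_params()] object.
#' @param jitter list of per-site jitter magnitudes: `peak_day_sd` (days, sd of
#'   normal jitter on both peak dates), `amplitude_lcv` (lognormal cv applied
#'   to both amplitudes), `width_lcv` (lognormal cv on widths). Set all to 0
#'   for identical sites.
#' @param censor_from_tv_homes if `TRUE`, each region's censor threshold is
#'   scaled by the inverse of its TV-homes count (small media markets lose more
#'   days to zero-censoring): `censor_threshold * median(tv_homes) / tv_homes`.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_site_years = 25, year = 2015, seed = 1,
                       pollen = pollen_model_params(),
                       search = search_model_params(),
                       missingness = missingness_params(),
                       jitter = list(peak_day_sd = 7, amplitude_lcv = 0.3,
                                     width_lcv = 0.15),
                       censor_from_tv_homes = FALSE) {
  stopifnot(inherits(pollen, "pollen_model_params"),
            inherits(search, "search_model_params"),
            inherits(missingness, "missingness_params"))
  if (n_site_years < 1) stop("field `n_site_years` must be >= 1", call. = FALSE)
  jd <- list(peak_day_sd = 0, amplitude_lcv = 0, width_lcv = 0)
  jd[names(jitter)] <- jitter
  structure(list(n_site_years = as.integer(n_site_years),
                 year = check_year(year), seed = as.integer(seed),
                 pollen = pollen, search = search, missingness = missingness,
                 jitter = jd, censor_from_tv_homes = isTRUE(censor_from_tv_homes)),
            class = "panel_spec")
}

check_nonneg <- function(p, fields) {
  for (f in fields) if (p[[f]] < 0) {
    stop(sprintf("field `%s` must be >= 0", f), call. = FALSE)
  }
}
check_positive <- function(p, fields) {
  for (f in fields) if (p[[f]] <= 0) {
    stop(sprintf("field `%s` must be > 0", f), call. = FALSE)
  }
}

# Unit-mean multiplicative lognormal noise with the given coefficient of
# variation; cv = 0 returns exact 1s (and consumes no random numbers).
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Deterministic seasonal mean of the pollen model
#'
#' The noise-free expected concentration on each day of the year:
#' `baseline + sum_i amplitude_i * exp(-(d - peak_i_day)^2 / (2 * width_i^2))`.
#' Useful as the latent reference when calibrating censoring thresholds.
#'
#' @param params a [pollen_model_params()] object.
#' @param year calendar year.
#' @return numeric vector of length `days_in_year(year)`.
#' @export
pollen_seasonal_mean <- function(params, year) {
  d <- seq_len(days_in_year(year))
  params$baseline +
    params$peak1_amplitude *
      exp(-(d - params$peak1_day)^2 / (2 * params$peak1_width_days^2)) +
    params$peak2_amplitude *
      exp(-(d - params$peak2_day)^2 / (2 * params$peak2_width_days^2))
}

#' Generate one synthetic year of daily pollen concentrations
#'
#' Draws a bimodal seasonal curve with multiplicative lognormal noise, then
#' blanks days according to the missingness model. Missing days carry `NA`,
#' never zero.
#'
#' @param params a [pollen_model_params()] object.
#' @param year calendar year.
#' @param missingness a [missingness_params()] object, or `NULL` for a fully
#'   observed year.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a `daily_series` of kind `"pollen"`.
#' @examples
#' s <- generate_pollen_year(pollen_model_params(noise_cv = 0), 2015,
#'                           missingness = NULL)
#' which.max(s$values)  # the early-season peak day
#' @export
generate_pollen_year <- function(params, year, missingness = NULL, seed = NULL) {
  stopifnot(inherits(params, "pollen_model_params"))
  year <- check_year(year)
  with_seed(seed, {
    mu <- pollen_seasonal_mean(params, year)
    values <- mu * lognormal_noise(length(mu), params$noise_cv)
    s <- daily_series(values, year, "pollen")
    if (!is.null(missingness)) s <- apply_missingness(s, missingness)
    s
  })
}

#' Blank days of a series according to a station-missingness model
#'
#' @param series a `daily_series`.
#' @param missingness a [missingness_params()] object.
#' @param seed optional integer seed.
#' @return the series with the selected days set to missing (`NA`).
#' @export
apply_missingness <- function(series, missingness, seed = NULL) {
  stopifnot(inherits(series, "daily_series"),
            inherits(missingness, "missingness_params"))
  with_seed(seed, {
    nd <- length(series$values)
    miss <- rep(FALSE, nd)
    wk <- weekend_days(series$year)
    if (missingness$weekend_missing_prob > 0) {
      miss[wk] <- stats::runif(length(wk)) < missingness$weekend_missing_prob
    }
    eg <- missingness$edge_gap_days
    if (eg[1] > 0) miss[seq_len(min(eg[1], nd))] <- TRUE
    if (eg[2] > 0) miss[seq.int(max(1L, nd - eg[2] + 1L), nd)] <- TRUE
    if (missingness$random_gap_rate > 0) {
      n_gaps <- stats::rpois(1, missingness$random_gap_rate)
      if (n_gaps > 0) {
        starts <- sample.int(nd, n_gaps, replace = TRUE)
        lens <- 1L + stats::rpois(n_gaps, missingness$random_gap_length_mean - 1)
        for (g in seq_len(n_gaps)) {
          miss[seq.int(starts[g], min(nd, starts[g] + lens[g] - 1L))] <- TRUE
        }
      }
    }
    values <- series$values
    values[miss] <- NA_real_
    set_values(series, values)
  })
}

#' Generate replicate search-volume series coupled to a pollen year
#'
#' Each replicate emulates one download of adjusted search volumes: the latent
#' daily volume is a lagged power-law response to pollen plus a baseline rate,
#' perturbed by shared daily noise and replicate-specific sampling noise;
#' latent values below the censoring threshold report as 0 before rescaling;
#' every replicate is independently rescaled to a maximum of 100 and rounded
#' half-up to integers.
#'
#' Interior missing pollen days are linearly interpolated before coupling
#' (searchers respond to the true airborne pollen, not to station reporting);
#' lagged days falling outside the year contribute 0 (off-season).
#'
#' @param pollen a `daily_series` of kind `"pollen"`.
#' @param params a [search_model_params()] object.
#' @param seed optional integer seed.
#' @return a list of `daily_series` of kind `"search"`, one per replicate.
#'   A replicate censored to all-zero carries attribute `all_zero = TRUE` and
#'   raises a warning.
#' @export
generate_search_year <- function(pollen, params, seed = NULL) {
  stopifnot(inherits(pollen, "daily_series"),
            inherits(params, "search_model_params"))
  with_seed(seed, {
    nd <- length(pollen$values)
    p <- pollen$values
    if (anyNA(p)) {
      obs <- which(!is.na(p))
      if (length(obs) >= 2) {
        p <- stats::approx(obs, p[obs], xout = seq_len(nd), rule = 2)$y
      } else {
        p[is.na(p)] <- 0
      }
    }
    src <- seq_len(nd) - params$lag_days
    p_lagged <- ifelse(src >= 1 & src <= nd, p[pmax(pmin(src, nd), 1L)], 0)
    latent_mean <- params$baseline_rate +
      params$response_scale * p_lagged^params$response_exponent
    day_noise <- lognormal_noise(nd, params$noise_cv)
    shared <- latent_mean * day_noise
    lapply(seq_len(params$n_replicates), function(r) {
      latent <- shared * lognormal_noise(nd, params$replicate_noise_cv)
      latent[latent < params$censor_threshold] <- 0
      mx <- max(latent)
      if (mx == 0) {
        warning("replicate fully censored: all search volumes are 0",
                call. = FALSE)
        s <- daily_series(rep(0, nd), pollen$year, "search")
        attr(s, "all_zero") <- TRUE
        return(s)
      }
      daily_series(round_half_up(latent * 100 / mx), pollen$year, "search")
    })
  })
}

# Round half away from zero (values here are non-negative), matching the
# integer appearance of the public search feed.
round_half_up <- function(x) floor(x + 0.5)

#' Generate a coupled panel of synthetic station/region site-years
#'
#' For each site, pollen-model parameters are jittered around the panel
#' defaults, a complete noisy pollen year is drawn, replicate search series
#' are coupled to it, and only then is station missingness applied to the
#' pollen record (stations failing to count does not silence searchers).
#' Station and region metadata (continental-U.S. coordinates, log-uniform
#' TV-homes) are attached; each station sits within 0.1 degrees of its region
#' centroid so the coordinate-matching rule pairs them.
#'
#' @param spec a [panel_spec()] object.
#' @return a `pollen_panel`: a list with elements `stations` (list of
#'   [station_year()]), `regions` (list of [region_year()]), and `spec`.
#' @examples
#' panel <- generate_panel(panel_spec(n_site_years = 3, seed = 42))
#' length(panel$stations)
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    n <- spec$n_site_years
    lat <- stats::runif(n, 25, 48)
    lon <- stats::runif(n, -124, -68)
    tv_homes <- round(exp(stats::runif(n, log(5e4), log(8e6))))
    d_lat <- stats::runif(n, -0.1, 0.1)
    d_lon <- stats::runif(n, -0.1, 0.1)
    jit <- spec$jitter
    med_tv <- stats::median(tv_homes)
    stations <- vector("list", n)
    regions <- vector("list", n)
    for (i in seq_len(n)) {
      pp <- spec$pollen
      if (jit$peak_day_sd > 0) {
        shift <- stats::rnorm(1, 0, jit$peak_day_sd)
        pp$peak1_day <- min(366, max(1, pp$peak1_day + shift))
        pp$peak2_day <- min(366, max(1, pp$peak2_day + shift))
      }
      if (jit$amplitude_lcv > 0) {
        f <- lognormal_noise(1, jit$amplitude_lcv)
        pp$peak1_amplitude <- pp$peak1_amplitude * f
        pp$peak2_amplitude <- pp$peak2_amplitude * f
      }
      if (jit$width_lcv > 0) {
        pp$peak1_width_days <- pp$peak1_width_days * lognormal_noise(1, jit$width_lcv)
        pp$peak2_width_days <- pp$peak2_width_days * lognormal_noise(1, jit$width_lcv)
      }
      sp <- spec$search
      if (spec$censor_from_tv_homes && sp$censor_threshold > 0) {
        sp$censor_threshold <- sp$censor_threshold * med_tv / tv_homes[i]
      }
      complete <- generate_pollen_year(pp, spec$year, missingness = NULL)
      reps <- suppressWarnings(generate_search_year(complete, sp))
      observed <- apply_missingness(complete, spec$missingness)
      sid <- sprintf("ST%03d", i)
      did <- sprintf("DMA%03d", i)
      stations[[i]] <- station_year(sid, lat[i], lon[i], observed)
      regions[[i]] <- region_year(did, lat[i] + d_lat[i], lon[i] + d_lon[i],
                                  tv_homes[i], reps)
    }
    structure(list(stations = stations, regions = regions, spec = spec),
              class = "pollen_panel")
  })
}

#' @export
print.pollen_panel <- function(x, ...) {
  cat(sprintf("<pollen_panel> %d site-years, year %d, seed %d\n",
              length(x$stations), x$spec$year, x$spec$seed))
  invisible(x)
}
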