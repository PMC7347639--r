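test_that("noiseless pollen year reproduces the Gaussian bump analytically", {
  p <- pollen_model_params(peak1_day = 100, peak1_width_days = 10,
                           peak1_amplitude = 1000, peak2_amplitude = 0,
                           noise_cv = 0, baseline = 0)
  s <- generate_pollen_year(p, 2015, missingness = NULL)
  expect_equal(s$values[100], 1000)
  expect_lt(s$values[250], 1)
  expect_equal(which.max(s$values), 100)
  # expected value matches the closed form on every day
  d <- seq_len(365)
  expect_equal(s$values, 1000 * exp(-(d - 100)^2 / (2 * 10^2)))
})

test_that("parameter validation names the offending field", {
  expect_error(pollen_model_params(noise_cv = -1), "noise_cv")
  expect_error(pollen_model_params(peak1_width_days = 0), "peak1_width_days")
  expect_error(pollen_model_params(peak1_amplitude = 10, peak2_amplitude = 10),
               "peak1_amplitude")
  expect_error(search_model_params(response_exponent = 0), "response_exponent")
  expect_error(search_model_params(n_replicates = 0), "n_replicates")
  expect_error(missingness_params(weekend_missing_prob = 1.5),
               "weekend_missing_prob")
  expect_error(generate_pollen_year(pollen_model_params(), 12.5), "year")
})

test_that("weekend missingness blanks exactly the calendar weekends", {
  m <- missingness_params(weekend_missing_prob = 1, edge_gap_days = c(0, 0),
                          random_gap_rate = 0, random_gap_length_mean = 1)
  s <- generate_pollen_year(pollen_model_params(), 2015, m, seed = 5)
  # independent calendar oracle: POSIXlt weekday of every 2015 date
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  wk <- which(as.POSIXlt(dates)$wday %in% c(0, 6))
  expect_length(wk, 104)
  expect_identical(which(is.na(s$values)), wk)
})

test_that("edge gaps and seeding behave deterministically", {
  m <- missingness_params(weekend_missing_prob = 0.5, edge_gap_days = c(7, 10),
                          random_gap_rate = 2, random_gap_length_mean = 3)
  s1 <- generate_pollen_year(pollen_model_params(), 2016, m, seed = 11)
  s2 <- generate_pollen_year(pollen_model_params(), 2016, m, seed = 11)
  expect_identical(s1, s2)
  expect_true(all(is.na(s1$values[1:7])))
  expect_true(all(is.na(s1$values[357:366])))  # leap year: 366 days
  s3 <- generate_pollen_year(pollen_model_params(), 2016, m, seed = 12)
  expect_false(identical(s1$values, s3$values))
})

test_that("noise-free search replicate is a rescaled monotone copy of pollen", {
  p <- generate_pollen_year(pollen_model_params(noise_cv = 0), 2015, NULL)
  sp <- search_model_params(lag_days = 0, response_exponent = 1,
                            baseline_rate = 0, noise_cv = 0,
                            censor_threshold = 0, n_replicates = 2,
                            replicate_noise_cv = 0)
  reps <- generate_search_year(p, sp, seed = 1)
  expect_length(reps, 2)
  for (r in reps) {
    expect_equal(max(r$values), 100)
    expect_true(all(r$values == floor(r$values)))
    # rounding ties the many near-zero off-season days; drop them before
    # asserting the monotone relationship
    keep <- which(r$values > 0)
    v <- rep(NA_real_, 365)
    v[keep] <- r$values[keep]
    rho <- spearman_rho(daily_series(v, 2015, "search"), p)
    expect_gte(rho$rho, 0.99)
    # integer rounding preserves order: search sorted by pollen is monotone
    expect_true(all(diff(r$values[order(p$values)]) >= 0))
  }
})

test_that("censoring above the latent maximum yields an all-zero flagged replicate", {
  p <- generate_pollen_year(pollen_model_params(noise_cv = 0), 2015, NULL)
  sp <- search_model_params(baseline_rate = 0, noise_cv = 0,
                            censor_threshold = 1e9, n_replicates = 1,
                            replicate_noise_cv = 0)
  expect_warning(reps <- generate_search_year(p, sp), "fully censored")
  expect_true(all(reps[[1]]$values == 0))
  expect_true(attr(reps[[1]], "all_zero"))
})

test_that("censoring at the latent median zeroes exactly the sub-median days", {
  p <- generate_pollen_year(pollen_model_params(noise_cv = 0, baseline = 5),
                            2015, NULL)
  # latent series recomputed independently from the closed form
  pp <- pollen_model_params(noise_cv = 0, baseline = 5)
  d <- seq_len(365)
  latent <- 10 + (pp$baseline +
    pp$peak1_amplitude * exp(-(d - pp$peak1_day)^2 / (2 * pp$peak1_width_days^2)) +
    pp$peak2_amplitude * exp(-(d - pp$peak2_day)^2 / (2 * pp$peak2_width_days^2)))
  thr <- stats::median(latent)
  sp <- search_model_params(lag_days = 0, response_exponent = 1,
                            baseline_rate = 10, noise_cv = 0,
                            censor_threshold = thr, n_replicates = 1,
                            replicate_noise_cv = 0)
  r <- generate_search_year(p, sp)[[1]]
  expect_identical(r$values == 0, latent < thr)
})

test_that("raising the censor threshold never decreases the zero-day count", {
  p <- generate_pollen_year(pollen_model_params(), 2015, NULL, seed = 3)
  zeros <- vapply(c(0, 5, 20, 80, 300), function(thr) {
    sp <- search_model_params(censor_threshold = thr, n_replicates = 1)
    r <- generate_search_year(p, sp, seed = 99)[[1]]
    sum(r$values == 0)
  }, numeric(1))
  expect_true(all(diff(zeros) >= 0))
})

test_that("every non-all-zero replicate has maximum exactly 100", {
  p <- generate_pollen_year(pollen_model_params(), 2015, NULL, seed = 8)
  reps <- generate_search_year(p, search_model_params(censor_threshold = 30),
                               seed = 21)
  for (r in reps) expect_equal(max(r$values), 100)
})

test_that("panels are reproducible and perfectly coupled when noise is off", {
  spec <- panel_spec(n_site_years = 3, seed = 42)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(p1, p2)
  expect_length(p1$stations, 3)

  quiet <- panel_spec(
    n_site_years = 3, seed = 7,
    pollen = pollen_model_params(noise_cv = 0),
    search = search_model_params(noise_cv = 0, replicate_noise_cv = 0,
                                 censor_threshold = 0, baseline_rate = 0,
                                 n_replicates = 1),
    missingness = missingness_params(0, c(0, 0), 0, 1),
    jitter = list(peak_day_sd = 0, amplitude_lcv = 0, width_lcv = 0))
  pq <- generate_panel(quiet)
  for (i in 1:3) {
    po <- pq$stations[[i]]$series
    se <- pq$regions[[i]]$averaged
    # perfect rank agreement up to integer-rounding ties: search values
    # sorted by pollen are non-decreasing, and rho = 1 on untied days
    expect_true(all(diff(se$values[order(po$values)]) >= 0))
    untied <- which(!(duplicated(se$values) |
                        duplicated(se$values, fromLast = TRUE)))
    if (length(untied) >= 3) {
      v <- rep(NA_real_, 365)
      v[untied] <- se$values[untied]
      expect_equal(spearman_rho(daily_series(v, 2015, "search"), po)$rho, 1)
    }
  }
})

test_that("zero-day fraction falls with log TV-homes under population-scaled censoring", {
  spec <- panel_spec(n_site_years = 40, seed = 13,
                     search = search_model_params(censor_threshold = 25),
                     censor_from_tv_homes = TRUE)
  panel <- generate_panel(spec)
  pct_zero <- vapply(panel$regions, function(rg) {
    mean(rg$averaged$values == 0, na.rm = TRUE) * 100
  }, numeric(1))
  log_tv <- log(vapply(panel$regions, `[[`, 0, "tv_homes"))
  fit <- oracle_ols(log_tv, pct_zero)   # closed-form least squares
  expect_lt(fit[["slope"]], 0)
})
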