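test_that("cumulative-fraction starts follow the running-sum rule", {
  v <- rep(0, 365); v[1:10] <- 10
  s <- daily_series(v, 2015, "pollen")
  out <- start_cumulative(s, 0.05)
  expect_equal(out$start_day, 1)       # day-1 cumulative 10 >= 5% of 100
  expect_equal(out$basis_total, 100)
  spike <- rep(0, 365); spike[50] <- 400
  for (f in c(0.025, 0.05, 0.5, 0.99)) {
    expect_equal(start_cumulative(daily_series(spike, 2015, "pollen"),
                                  f)$start_day, 50)
  }
  zero <- start_cumulative(daily_series(rep(0, 365), 2015, "pollen"), 0.05)
  expect_true(is.na(zero$start_day))
  expect_equal(zero$flag, "zero_total")
})

test_that("cumulative starts equal the scan oracle and order by fraction", {
  set.seed(12)
  for (rep in 1:20) {
    v <- random_year_values()
    s <- daily_series(v, 2015, "pollen")
    d5 <- start_cumulative(s, 0.05)$start_day
    d25 <- start_cumulative(s, 0.025)$start_day
    expect_equal(d5, oracle_start_cumulative(v, 0.05), ignore_attr = TRUE)
    expect_equal(d25, oracle_start_cumulative(v, 0.025), ignore_attr = TRUE)
    expect_lte(d25, d5)
  }
})

test_that("cumulative starts are invariant to positive rescaling", {
  set.seed(13)
  v <- random_year_values()
  s <- daily_series(v, 2015, "pollen")
  base <- start_cumulative(s, 0.05)$start_day
  for (k in c(0.01, 3, 250)) {
    expect_equal(start_cumulative(daily_series(v * k, 2015, "pollen"),
                                  0.05)$start_day, base)
  }
})

test_that("consecutive-day starts find the first qualifying run", {
  v <- rep(0, 365); v[30:33] <- 5
  s <- daily_series(v, 2015, "pollen")
  expect_equal(start_consecutive(s, 4)$start_day, 30)
  alt <- rep(c(1, 0), length.out = 365)
  expect_true(is.na(start_consecutive(daily_series(alt, 2015, "pollen"),
                                      4)$start_day))
  # a run interrupted by a missing day does not qualify
  v2 <- rep(0, 365); v2[29:40] <- 5; v2[32] <- NA
  expect_equal(start_consecutive(daily_series(v2, 2015, "pollen"), 4)$start_day,
               33)
  set.seed(14)
  for (rep in 1:20) {
    v <- random_year_values(miss_prob = 0.4)
    v[v < 1] <- 0
    got <- start_consecutive(daily_series(v, 2015, "pollen"), 4)$start_day
    expect_equal(got, oracle_start_consecutive(v, 4), ignore_attr = TRUE)
  }
})

test_that("absolute-threshold starts share the high-day definition", {
  v <- rep(100, 365); v[81] <- 200
  s <- daily_series(v, 2015, "pollen")
  expect_equal(start_absolute(s, 200)$start_day, 81)
  expect_true(is.na(start_absolute(s, 200, comparator = ">")$start_day))
  expect_equal(start_absolute(s, 200)$start_day,
               first_high_day(s, 200), ignore_attr = TRUE)
})

test_that("search and pollen starts coincide for proportional series", {
  set.seed(15)
  p <- generate_pollen_year(pollen_model_params(peak2_amplitude = 0,
                                                baseline = 0), 2015, NULL)
  win <- c(1L, 181L)
  # search exactly proportional to pollen inside the window (cumulative
  # fractions are scale-invariant)
  sv <- rep(NA_real_, 365)
  sv[1:181] <- pmin(100, 100 * p$values[1:181] / max(p$values[1:181]))
  search <- daily_series(sv, 2015, "search")
  defn <- start_definition("cumulative_fraction", fraction = 0.05,
                           variant = "raw")
  cfg <- transform_config(window = win)
  gt <- gt_season_start(search, defn, cfg)
  nab <- start_cumulative(p, 0.05, total_window = win)
  expect_equal(gt$start_day, nab$start_day)
})

test_that("a circular shift of the search series moves the start by the lag", {
  set.seed(16)
  p <- generate_pollen_year(pollen_model_params(peak2_amplitude = 0,
                                                baseline = 0), 2015, NULL)
  win <- 1:181
  shifted <- rep(NA_real_, 365)
  shifted[win] <- p$values[((win - 1 - 7) %% 181) + 1]  # 7 days later
  delta <- start_cumulative(daily_series(shifted, 2015, "pollen"), 0.05,
                            total_window = c(1, 181))$start_day -
    start_cumulative(p, 0.05, total_window = c(1, 181))$start_day
  expect_equal(delta, 7)
})

test_that("a constant search floor pulls the estimated start earlier", {
  set.seed(17)
  p <- generate_pollen_year(pollen_model_params(peak2_amplitude = 0,
                                                baseline = 0), 2015, NULL)
  base_start <- start_cumulative(p, 0.05, total_window = c(1, 181))$start_day
  floored <- daily_series(p$values + 50, 2015, "pollen")
  floor_start <- start_cumulative(floored, 0.05,
                                  total_window = c(1, 181))$start_day
  expect_lt(floor_start, base_start)
})

test_that("noiseless estimators recover the planted onset exactly", {
  p <- pollen_model_params(peak1_day = 100, peak1_width_days = 10,
                           peak1_amplitude = 1000, peak2_amplitude = 0,
                           noise_cv = 0, baseline = 0)
  s <- generate_pollen_year(p, 2015, NULL)
  # oracle on the analytic series: identical closed form as the generator
  d <- seq_len(365)
  analytic <- 1000 * exp(-(d - 100)^2 / (2 * 100))
  expect_equal(start_cumulative(s, 0.05)$start_day,
               oracle_start_cumulative(analytic, 0.05), ignore_attr = TRUE)
  expect_equal(start_absolute(s, 200)$start_day,
               oracle_start_absolute(analytic, 200), ignore_attr = TRUE)
  expect_equal(start_consecutive(s, 4)$start_day,
               oracle_start_consecutive(analytic, 4), ignore_attr = TRUE)
})

test_that("discrepancy analysis recovers zero delta for identical sources", {
  # search replicates proportional to pollen, no censoring, no noise
  spec <- panel_spec(
    n_site_years = 5, seed = 23,
    pollen = pollen_model_params(noise_cv = 0.2, peak2_amplitude = 0,
                                 baseline = 0),
    search = search_model_params(noise_cv = 0, replicate_noise_cv = 0,
                                 baseline_rate = 0, censor_threshold = 0,
                                 n_replicates = 1),
    missingness = missingness_params(0, c(0, 0), 0, 1))
  panel <- generate_panel(spec)
  out <- discrepancy_analysis(panel, variants = "raw")
  expect_equal(nrow(out$records), 5)
  # integer rounding of the 0-100 rescale can move the 5% crossing by a day
  expect_true(all(abs(out$records$delta_days) <= 1))
  expect_lte(abs(out$summary$median_delta[out$summary$tier == "all"]), 1)
})

test_that("tier membership follows the planted metadata", {
  spec <- panel_spec(n_site_years = 8, seed = 29,
                     missingness = missingness_params(0, c(0, 0), 0, 1))
  panel <- generate_panel(spec)
  # plant two stations starting late in the year (first data day > 31)
  for (i in 1:2) {
    v <- panel$stations[[i]]$series$values
    v[1:45] <- NA
    panel$stations[[i]]$series <- daily_series(v, 2015, "pollen")
  }
  out <- discrepancy_analysis(panel, variants = "raw")
  rec <- out$records
  late <- rec$station_id %in% c("ST001", "ST002")
  expect_true(all(!rec$tier_early_nab[late]))
  expect_true(all(rec$tier_early_nab[!late]))
  expect_true(all(rec$tier_all))
  # tier (c) is a subset of tier (b)
  expect_true(all(!rec$tier_low_gt_missing | rec$tier_early_nab))
})

test_that("previous-year baseline uses the same station's prior year", {
  mk_station <- function(id, year, peak_day) {
    p <- pollen_model_params(peak1_day = peak_day, peak2_amplitude = 0,
                             noise_cv = 0, baseline = 0)
    station_year(id, 40, -100, generate_pollen_year(p, year, NULL))
  }
  mk_region <- function(id, year, station) {
    sp <- search_model_params(noise_cv = 0, replicate_noise_cv = 0,
                              baseline_rate = 0, censor_threshold = 0,
                              n_replicates = 1)
    region_year(id, 40, -100, 1e5,
                generate_search_year(station$series, sp))
  }
  s14 <- mk_station("A", 2014, 95); s15 <- mk_station("A", 2015, 102)
  panel <- list(stations = list(s14, s15),
                regions = list(mk_region("D", 2014, s14),
                               mk_region("D", 2015, s15)))
  out <- discrepancy_analysis(panel, variants = "raw")
  rec <- out$records
  r15 <- rec[rec$year == 2015, ]
  r14 <- rec[rec$year == 2014, ]
  expect_true(is.na(r14$prev_year_nab_start))
  expect_equal(r15$prev_year_nab_start, r14$nab_start)
  expect_equal(r15$prev_year_delta, r15$nab_start - r14$nab_start)
})
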