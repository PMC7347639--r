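# Hand-labelled boundary fixtures for the station-year inclusion rules.
# Each template is built directly (no generator code) and labelled by hand
# from the rule wording: excluded iff > 60% missing days, or a missing run
# longer than 4 days intersecting [first_high - 10, first_high + 10], or no
# data at all in the January--June analysis window.

boundary_templates <- function(scale = 1) {
  year <- 2015
  base <- function() {
    v <- rep(10 * scale, 365)
    v[100] <- 300 * scale  # first (and only) high day at day 100
    v
  }
  tpl <- list()
  add <- function(name, values, included, reasons = character()) {
    tpl[[length(tpl) + 1L]] <<- list(
      name = name, series = pollenproxy::daily_series(values, year, "pollen"),
      included = included, reasons = reasons)
  }
  # fully observed
  add("clean", base(), TRUE)
  # exactly 60% (219/365) missing, runs of <= 3 days, core [80,120] observed
  sixty <- function(n_missing) {
    v <- base()
    cand <- setdiff(1:365, 80:120)
    md <- cand[cand %% 4 != 0]
    v[md[seq_len(n_missing)]] <- NA_real_
    v
  }
  add("exactly_60pct", sixty(219L), TRUE)                 # 60% is not "more than 60%"
  add("61pct", sixty(223L), FALSE, "missingness")         # 223/365 = 61.1%
  v <- base(); v[96:99] <- NA_real_
  add("gap4_at_high", v, TRUE)                            # 4 days is not "over four"
  v <- base(); v[95:99] <- NA_real_
  add("gap5_at_high", v, FALSE, "gap_near_first_high")
  v <- base(); v[85:94] <- NA_real_
  add("gap10_overlapping", v, FALSE, "gap_near_first_high")
  v <- base(); v[200:209] <- NA_real_
  add("gap10_far_from_high", v, TRUE)                     # outside [90, 110]
  v <- rep(NA_real_, 365); v[182:365] <- 10 * scale
  add("no_early_data", v, FALSE, "no_data_in_window")
  v <- rep(50 * scale, 365); v[95:97] <- NA_real_
  add("no_high_day", v, TRUE)                             # near-high rule skipped
  v <- base(); v[83:88] <- NA_real_
  add("gap6_ending_before_interval", v, TRUE)             # ends day 88 < 90
  v <- base(); v[86:90] <- NA_real_
  add("gap5_touching_interval_edge", v, FALSE, "gap_near_first_high")
  tpl
}

# 44 station-years: the 11 templates at 4 value scalings (labels unchanged).
boundary_panel <- function() {
  out <- list()
  for (scale in c(1, 1.2, 1.5, 1.9)) {
    out <- c(out, boundary_templates(scale))
  }
  out
}
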