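---
title: "Validating search volumes as a pollen proxy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating search volumes as a pollen proxy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenproxy)
```

## The problem

Daily airborne-pollen concentrations in the U.S. are measured by a sparse
network of volunteer counting stations: manual microscopy, two hours a day,
typically three days a week, at fewer than seventy locations. Search-engine
interest in the term "pollen", reported daily per media-market region on a
relative 0--100 scale, is a candidate proxy in the large regions with no
counting station. `pollenproxy` implements the validation analysis for that
proxy: it quantifies, per station-year, how well the regional search series
tracks the observed early-season (January--June) pollen series, stratifies
that agreement by the two site characteristics that govern it — the
availability of search data and the prominence of its seasonal peak — and
compares season onset dates estimated from each source.

Because station pollen records are distributed only on request, the package
ships a synthetic generator of coupled pollen/search panels with the
statistical structure the analysis assumes. Every stage of the pipeline is
exercised and tested against these panels; the same code runs unchanged on
real CSV exports.

## The data model

A `daily_series` is one calendar year of dated daily values with explicit
missingness (`NA` is "not measured", a stored `0` is "reported zero" — the
two are never conflated). Pollen series are concentrations in grains/m³;
search series are integer adjusted volumes in [0, 100]. The analysis unit is
the *station-year* (or region-year): one site, one calendar year.

Stations pair with search regions by coordinates: both latitude and
longitude must differ by at most 0.3 decimal degrees (a per-axis test, not
great-circle distance); among multiple candidates the region with the
smallest Chebyshev distance `max(|Δlat|, |Δlon|)` wins. Search downloads are
replicated (10 by default) and averaged day-wise, zeros counting as zeros; a
day is missing in the average only when no replicate observed it.

## Quality screening

Two compliance proxies decide whether a station-year enters the analysis,
assessed over the full calendar year:

* more than 60% of days missing a pollen record excludes the station-year
  (exactly 60% is retained — the rule is a strict inequality);
* a run of more than four consecutive missing days that intersects the
  window ±10 days around the first *high* pollen day (first day at or above
  200 grains/m³) excludes it (a 4-day run is retained). The run's full
  length is compared against the bound, not just its overlap with the ±10
  window; when no high day exists the rule is skipped rather than failed.

A station-year with no data at all in the analysis window is excluded with
its own reason code, so either accounting order can be reconstructed from
the per-reason columns of `quality_table()`.

For search series, the missingness metric counts reported zeros as missing:
the feed suppresses volumes below a quantification threshold and displays
them as 0, so a zero is structurally closer to "not measured" than to a
measurement. `percent_missing(..., zero_as_missing = )` makes the choice
explicit.

## The transform stack

The correlation pathway is: restrict to the January--June window → normalise
pollen to a maximum of 100 per year (putting it on the search-volume scale)
→ `log(v + 1)` → light LOWESS smoothing (bandwidth 0.1). Spearman's rho is
invariant to the monotone steps, so the order of normalisation and log
transform is immaterial for the correlation itself; it matters only for
plots and for onset estimates computed on smoothed variants, which is why
the chain is configurable in `transform_config()`.

The smoother is classical LOWESS: for each observed day, the nearest
`ceiling(bandwidth * n)` observed days form the neighbourhood, and a
tricube-weighted local linear fit is evaluated at that day. The bandwidth is
the *fraction of observed points* per neighbourhood, so it adapts to
missingness. Design choices worth stating:

* degree-1 local fits with tricube weights — the canonical form, and the
  one that reproduces linear data exactly (the basis of several tests);
* no robustness iterations by default (`iter = 0`); an iteration count is
  exposed for sensitivity runs;
* fitted values are returned at observed days only; missing days stay
  missing through every transform;
* `log_offset` defaults to 1 because both sources legitimately contain
  zeros; any positive offset is accepted;
* ties in neighbour distance are resolved by the distance cutoff itself
  (all points at the q-th-smallest distance enter; tricube weight vanishes
  at the cutoff), so the fit is deterministic.

The test suite checks the smoother pointwise (tolerance 1e-8) against an
independent brute-force weighted-regression oracle, and against the
reference implementation in `stats::lowess` (with its interpolation and
robustness features disabled) on a grid where the two neighbourhood
conventions coincide.

## Association analysis

Per matched pair, `association_analysis()` reports Spearman's rho over
jointly observed window days (ties get average ranks; pairs with fewer than
3 joint days are flagged, not reported), together with the covariates used
for stratification: percent search days missing (zeros counted as missing),
percent search days zero, and the *peak signal-to-noise* statistic — the
mean absolute difference between the raw search series and its heavily
smoothed (bandwidth 0.8) LOWESS baseline. A sharp seasonal peak deviates
strongly from the smooth baseline; a flat series does not.

Censored zero days are excluded from the pairwise-complete set by default
(they carry no quantified signal); `keep_censored_zeros = TRUE` retains them
as values, which is the faithful emulation of correlating the as-downloaded
series. The difference matters: excluding zeros removes exactly the noisy
low-volume days, so censoring alone barely moves rho; retaining them lets
the mass of tied zeros deflate the rank correlation the way sparse regions
show in practice. Both modes are first-class.

Quartile stratification uses type-7 (linear-interpolation) percentiles of
the covariate as cutoffs, assignment by `value ≤ cutoff`, and reports the
median and IQR of rho per quartile. Group contrasts use pooled-variance
Student's t (Welch by flag); covariate screens are univariate OLS with
normal-theory slope intervals, with a log-covariate option for the
TV-homes (population/media-size) screen.

## Season starts

Three onset-rule families are implemented: cumulative fraction of the
annual total (5% and 2.5% in common use), first run of `k` consecutive days
with recorded pollen (default 4), and first day at an absolute
concentration (default 200 grains/m³, `>=` by default to match the "high
day" definition, `>` by flag). Missing days contribute zero to cumulative
sums — no imputation anywhere in the package.

For station series the cumulative total spans the full calendar year; for
search series it spans the January--June window, because search data are
only collected for the early season. The discrepancy analysis applies the
5% rule to both sources under three data variants (raw, smoothed,
log-smoothed — the variant transforms both series, not just one), reports
`delta = search start − pollen start` (negative: searches lead), and
summarises delta across cumulatively applied inclusion tiers: all included
site-years; those whose pollen record begins within January; those with
under 20% missing search days. A previous-year baseline (current vs prior
year pollen start at the same station) calibrates how much year-to-year
drift a "free" predictor already carries.

Two behaviours of the cumulative rule are worth knowing. It is invariant to
positive rescaling of the series (so the 0--100 rescaling of search data is
harmless), and a constant search floor — baseline interest unrelated to
pollen — accumulates mass before the season and pulls the estimated start
*earlier*. Log transformation compresses the peak relative to the floor and
amplifies the same effect. That is the package's mechanism for the
consistently early search-derived starts seen in the reports.

## The synthetic generator

`generate_pollen_year()` draws a bimodal seasonal mean (two Gaussian bumps
in day-of-year: a dominant early tree-pollen peak, defaults day 100,
width 15, amplitude 1000 grains/m³; a smaller late peak, day 245, width 25,
amplitude 250; baseline 2) multiplied by unit-mean lognormal daily noise
(default cv 0.4). Gaussians were chosen because a two-parameter bump
(date, width) is the minimal shape with controllable onset; concentrations
are non-negative and right-skewed, hence multiplicative lognormal noise.
Missingness mimics volunteer stations: weekends unmeasured with probability
0.6, optional year-edge gaps, Poisson-distributed random gaps of mean
length 3 days.

`generate_search_year()` builds each download replicate as
`noise × (baseline_rate + response_scale × pollen(d − lag)^exponent)`:
a lagged monotone power-law response (defaults: lag 0, exponent 1, scale 1,
baseline 20) with shared day-level noise (cv 0.3) and replicate-specific
sampling noise (cv 0.15). Latent values below the censoring threshold
report as 0 *before* rescaling — matching the suppression of low absolute
volumes — then each replicate is independently rescaled to a maximum of
exactly 100 and rounded half-up to integers. A fully censored replicate
returns as an all-zero series with a warning flag rather than an error,
because that is what sparse regions actually produce. `generate_panel()`
jitters the pollen parameters per site (peak date sd 7 days, amplitude and
width lognormal cv 0.3/0.15), attaches continental-U.S. coordinates and
log-uniform TV-homes (5e4--8e6), and can scale each region's censoring
threshold inversely with TV-homes. Search is coupled to the *complete*
pollen series before station missingness is applied: stations failing to
count does not stop people searching.

What the generator does *not* emulate: taxon-specific pollen,
meteorology-driven release and transport, true search psychology (the
power-law coupling is a stand-in, uncalibrated against any measured
dose-response), spatial correlation between neighbouring sites, and
year-over-year trends in search adoption. Tests passing on these panels
therefore demonstrate that the *pipeline* recovers planted structure under
the stated noise model — not that real search data carry that structure.

## The validation experiments

The packaged experiments (also recomputed by `scripts/acceptance.R`) use
problem sizes chosen to keep a full run within a couple of minutes on one
core while leaving medians stable: 100 site-years per censoring level, 60
per volume level, 50 for lag recovery, 200 for the end-to-end run.

*Censoring levels.* Four panels target ≈0/15/35/60% zero days. Regional
volume drives both censoring and noise, so the levels jointly raise day
noise (cv 0.10→0.50) and replicate noise (0.10→0.40); thresholds are set
analytically as the latent-quantile at the target fraction, inflated by the
expected log-maximum of the 10 replicate factors (an averaged day is zero
only when *every* replicate censors). Correlations here retain zeros, since
the mechanism under test is the as-downloaded series degrading. Median rho
declines strictly across levels and exceeds 0.95 at the clean level.

*Peak signal strength.* Three panels span a 3× range of latent response
amplitude against a fixed censoring floor, with sampling noise inversely
scaled (cv 1.2/0.6/0.3): sparse incoherent replicates flatten under 10×
averaging (low SNR, low rho), coherent peaks survive (high SNR, high rho).
Median SNR rises strictly with planted prominence and median rho rises
across SNR quartiles.

*Lag recovery.* Search generated as pollen led by 10 days, unimodal pollen,
no censoring or missingness — the clean isolation of the lag (with a
bimodal curve the different accumulation windows of the two sources would
add a systematic offset unrelated to lag). The median start-date delta
recovers −10 days; adding a constant search floor makes it strictly more
negative.

## Limitations

The package validates a proxy, it does not produce pollen forecasts. All
thresholds (60%, 4 days, ±10 days, 200 grains/m³, bandwidths 0.1/0.8, 5%)
are conventions, exposed as parameters rather than constants. Rank
correlation on smoothed series is structurally optimistic: smoothing makes
both series slowly varying in time, which inflates rank agreement for any
two curves peaking in the same season; the raw-series rho reported
alongside (`rho_raw`) is the conservative companion. Finally, the
generator's noise model is stationary within a year, whereas real search
noise is burstier around media events — censoring-level results should be
read as directionally, not numerically, transferable.
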