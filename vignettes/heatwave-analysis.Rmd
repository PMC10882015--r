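---
title: "Percentile-run heatwave analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percentile-run heatwave analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatrends)
```

## The problem

Humid tropical regions such as Peninsular Malaysia have a small annual
temperature range (monthly-mean daily maxima span roughly 28–31 °C), so
absolute-threshold heatwave definitions borrowed from mid-latitude practice
either never fire or fire constantly. The standard alternative is a
*relative* definition: a heatwave at a grid cell is a run of **three or more
consecutive days** on which daily maximum 2-m temperature (Tmax) exceeds a
high percentile (95th, 97.5th or 99th) of that cell's own climatology over a
fixed reference period (1961–1990, the conventional climate-normal window).
A stricter *day–night* variant additionally requires daily minimum
temperature (Tmin) to exceed its own percentile threshold on the same days,
reflecting the epidemiological importance of hot nights.

`heatrends` implements that definition end to end on gridded daily
temperature: per-cell thresholds, event extraction, nine annual indices,
decadal trend estimation that is honest under long-term persistence, and
population-exposure overlays — together with a synthetic-data generator so
that every stage is testable without external downloads.

## Detection

**Thresholds.** Per cell, the empirical quantile of all daily values in the
reference window, pooled across the calendar (`pool = "pooled"`). A pooled
climatology is defensible here precisely because the seasonal cycle is weak;
for strongly seasonal domains a day-of-year windowed variant
(`pool = "doy_window"`, ±15 days) is provided. Quantiles use linear
interpolation between order statistics (`stats::quantile` type 7), fixed and
documented so results are bit-reproducible. Cells with more than
`max_missing_fraction` (default 10%) missing reference days get `NA`
thresholds and are excluded downstream.

**Events.** The daily exceedance mask uses the *strict* inequality
(Tmax > threshold). Runs are maximal sequences of exceedance days; a single
non-exceedance or missing day breaks a run (missing days can never belong to
an event). Runs of at least `min_run_days` (default 3) become events carrying
their peak Tmax and cumulative exceedance `sum(Tmax − threshold)` over event
days. Events that straddle 31 December are attributed to the year containing
their **start** day — the simplest unambiguous rule, and events rarely
straddle the year boundary in a monsoon climate where the hot season is
centred mid-year. Both the strictness of the inequality and the pooling
choice are exposed as arguments rather than hard-coded, since published
analyses frequently leave them unstated.

**National alert levels.** Independently of the percentile definition,
`classify_malaysian_level()` reproduces the three-band national scale for a
3-day window of daily Tmax, decided by the window minimum *m*: level 1
("Alert") for 35 ≤ *m* < 37 °C, level 2 (heatwave announcement) for
37 ≤ *m* ≤ 40 °C, level 3 (emergency) for *m* > 40 °C. The published bands
overlap at 37 °C; we assign the edge to the higher band so the bands
partition the line, and 40 °C to level 2 because level 3 is stated as
"exceeds 40".

## Annual indices

Nine indices summarise each year under each percentile definition
(`annual_summary()`, `index_timeseries()`):

| Index | Meaning | Unit |
|---|---|---|
| AHW  | area of land cells hosting ≥ 1 day-mode event | km² |
| DHW  | maximum event duration | days |
| THW  | peak Tmax over event days | °C |
| CTHW | total cumulative exceedance over events | °C |
| HWI  | heatwave index (see below) | – |
| AHWN | area with joint day–night events | % of land area |
| DHWN, THWN, CTHWN | night-time counterparts of DHW/THW/CTHW | |

Cell areas use the spherical-Earth band formula
`R² · Δλ · (sin φ_top − sin φ_bottom)` with `R = 6371` km, so AHW is
latitude-weighted exactly. Because day–night exceedance implies day
exceedance at equal percentiles, AHWN (as area) never exceeds AHW, and all
area indices are monotone non-increasing in the percentile.

**HWI.** Verbal definitions of a "heatwave index" conflate "fraction of area
affected" with "× number of heatwaves". We implement
`HWI = Σ over day-mode events of (event cell's area / total land area)`,
i.e. the mean affected fraction multiplied by the event count. It is 1.0
exactly when every land cell hosts exactly one event, and grows with both
extent and frequency. Note the event count is a *cell-event* count: events
are per cell, and no spatial merging of contiguous cells into synoptic
"events" is attempted, since any merging rule would be an invention the data
cannot arbitrate. HWI values therefore scale with grid resolution; compare
them only across analyses on the same grid.

**THW/CTHW variants.** THW is the maximum event peak by default
(`peak_stat = "max"`); a mean-over-events variant is available because both
aggregations appear in the literature. CTHW sums the cumulative *exceedance*
(°C·day above threshold) rather than raw Tmax: exceedance is comparable
across cells with different climatologies, whereas summed raw temperatures
mostly measure event-day counts.

## Trends under long-term persistence

Annual climate series are frequently long-range dependent; treating them as
independent inflates the Mann–Kendall (MK) statistic's significance. The
package pairs Sen's slope with the MK test *under the scaling hypothesis*
(`mmk_test()`):

1. **Sen's slope**: median of all pairwise slopes
   `(y_j − y_i)/(t_j − t_i)`, the robust trend magnitude; reported per step
   and per decade (`slope_per_decade = 10 × sen_slope` for annual series).
2. **MK statistic**: `S = Σ_{i<j} sign(y_j − y_i)` with the classical
   tie-corrected variance `var0 = [n(n−1)(2n+5) − Σ_t t(t−1)(2t+5)]/18`.
3. **Hurst estimation** (`estimate_hurst()`): the series is detrended by its
   Sen slope (so a genuine trend is not mistaken for persistence), ranks are
   converted to normal scores `qnorm(rank/(n+1))`, and H is estimated by
   maximising the exact Gaussian log-likelihood under the fractional
   Gaussian noise (fGn) correlation matrix, whose lag-l autocorrelation is
   `ρ_l = ½(|l+1|^{2H} − 2|l|^{2H} + |l−1|^{2H})`.
   The one-dimensional search runs over H ∈ (0.50, 0.98); the likelihood is
   evaluated in O(n²) by Levinson–Durbin whitening for gap-free series and
   by Cholesky factorisation when years are missing. Significance of H
   compares the estimate with the published approximate null moments of the
   estimator on white noise (mean `0.5 − 2.87 n^{−0.9067}`, sd
   `0.77654 n^{−1/2} − 0.0062`), one-sided, since only H > 0.5 inflates the
   variance.
4. **Scaled variance** (`variance_scaled()`): when H is significant, the
   variance of S is recomputed as the quadruple sum over index pairs of
   `(2/π)·arcsin` of the fGn correlation contrast — exactly `var0` again
   when H = 0.5 — multiplied by the published empirical bias-correction
   polynomial `B(H, n)` that compensates for using an *estimated* H
   (`bias_correction = FALSE` disables it for sensitivity checks). The sum
   is O(n⁴) and is computed in compiled code.
5. **Decision**: the continuity-corrected deviate uses `(S − 1)` for S > 0
   and `(S + 1)` for S < 0. (Printed formulations sometimes show `(S − 1)`
   in both branches; that breaks the antisymmetry `Z(−y) = −Z(−y)` and is
   implemented here as the standard symmetric correction.) Two-sided normal
   p-values, α = 0.05.

When H is not significant (`ltp = "auto"`, the default) the result is
*exactly* the classical MK test, so the correction can only widen, never
narrow, confidence. `ltp = "always"`/`"never"` force either path, because
whether published analyses corrected every series or only H-significant ones
is often unknowable; `trend_table()` reports which path fired per series.

Calibration, verified in the test suite: on iid Gaussian noise at n = 73 the
empirical size is within [0.03, 0.07] at α = 0.05; on trend-free fGn with
H = 0.8 the classical test over-rejects by more than a factor of two
relative to the corrected test; on fGn with H = 0.8 at n = 1000 the mean
absolute error of Ĥ is below 0.1 (observed ≈ 0.02).

## Population exposure

`exposure_series()` counts the population living in cells hosting at least
one event in a year — a person counts once per year regardless of event
count or duration (a person-days variant is available via `person_days =
TRUE`). Fine population rasters are aggregated to the analysis grid by
fractional-area overlap weighting (`aggregate_population_to_grid()`), which
reduces to an exact block sum for nested grids and skips NA (nodata) fine
cells, matching the convention of weighted totals over non-NA cells.
Population years are matched exactly by default; `nearest_year = TRUE`
enables a logged fallback, with ties resolved to the earlier year. Exposure
uses day-mode events by default — the common reading of definitions phrased
in terms of Tmax percentiles — with day–night available.

## The synthetic-data generator

`generate_daily_temperature()` emulates the statistical structure the
analysis assumes, not any particular reanalysis:

- **Seasonal cycle**: 12 monthly means mapped to day-of-year. Defaults are a
  smooth humid-tropical cycle anchored at the observed extremes for
  Peninsular Malaysia (Tmax: December 28.1 °C, April 30.8 °C; Tmin: January
  21.8 °C, May 23.3 °C); the intermediate months are the package's own
  choice of a smooth interpolating cycle, since only the extremes are
  commonly reported. `seasonal_interp = "linear"` (default) interpolates
  periodically between month midpoints; `"step"` holds each month constant,
  which is convenient when a test wants every December day to equal the
  December mean exactly.
- **Anomalies**: per cell independent daily series — `"iid"`, `"ar1"`
  (marginal sd equal to `noise_sd`), or `"fgn"` with Hurst exponent
  `hurst_H`. The fGn generator (`generate_fgn()`) is exact: circulant
  embedding (Davies–Harte) when the embedding is non-negative definite,
  Cholesky on the fGn correlation matrix otherwise, with the method
  reported. The default anomaly persistence (`ar1_phi = 0.6` when AR(1) is
  selected) is a test-convenience value, not a fitted one: daily-anomaly
  persistence for the region is not commonly published.
- **Trend**: linear, `trend_per_decade` (default 0.18 °C/decade, the
  reported long-term warming rate for the region).
- **Tmin**: its own cycle plus the *shared* anomaly plus an independent
  offset (`diurnal_offset_sd`), clipped so Tmax ≥ Tmin holds cell-day-wise.
  The shared anomaly makes joint day–night exceedance possible at realistic
  rates; temperature data do not constrain the Tmax–Tmin dependence more
  finely than that.
- **Space**: a deterministic latitudinal gradient is available
  (`lat_gradient`, °C per degree latitude) but defaults to 0 so that
  cell-level expectations in examples hold at every cell; anomalies are
  spatially independent.
- **Calendar**: 365-day no-leap years, removing leap-day special cases from
  synthetic tests; the file reader preserves true calendars for real data.

`generate_population()` distributes a fixed total multinomially over a
Gaussian-mixture "city" weight surface on a grid `fine_factor` times finer
than the analysis grid, with a configurable NA (nodata) fraction; non-NA
counts sum exactly to the requested total.

What the generator does **not** emulate: data-assimilation artefacts,
topographic temperature fields, spatially correlated anomalies (available
only as independent cells), humidity, or demographic structure. Passing
tests on synthetic data therefore demonstrate the *algorithms* — threshold
arithmetic, run logic, index accounting, trend calibration, exposure
overlays — not fidelity to any particular reanalysis product.

## Numerical and interface choices

- Latitudes are normalised to ascending on read (reanalysis files often ship
  descending), and Kelvin inputs are converted using the declared units with
  an explicit conflict check against any caller override.
- Grid regularity is enforced to 10⁻⁶ degrees; coordinates are cell centers;
  indices are 1-based (R convention) everywhere, including event tables.
- CSV exports print doubles at 17 significant digits with a C-locale decimal
  point, so files round-trip bit-exactly.
- Degenerate trend series (constant, or variance zero after ties) return
  `p = 1` with a `degenerate` flag rather than an error, so a trend table
  over many indices never aborts on an all-zero series.
- If the likelihood search for H ends at the upper boundary, the result is
  flagged, H is treated as not significant, and a warning is raised — an
  annual series that looks like H ≈ 1 is better treated as "no reliable
  correction" than silently given an enormous variance.
- If the scaled variance is numerically non-positive, it is floored at the
  classical variance with a warning.

Problem sizes in the shipped tests are chosen to make the statistical checks
sharp but quick: the full calibration uses 2,000 replicates at n = 73 for
size, 400 replicates for the persistence comparison, 200 replicates at
n = 1000 for Hurst recovery, and small grids (2×2 to 3×3 cells, 8–45 years)
for the cube-level pipelines, which already exercise every code path.

## Known limitations

- Events are per-cell; spatially merged multi-cell events (and hence
  synoptic event counts) are out of scope, and HWI inherits grid-resolution
  dependence from that.
- The LTP correction assumes the fGn correlation family; other dependence
  structures (e.g. regime shifts) will be partially absorbed into Ĥ.
- Thresholds from short reference windows are noisy order statistics; the
  package does not propagate threshold uncertainty into the indices.
- File exchange uses plain-text formats (a self-describing CSV cube for
  temperature, ESRI ASCII grids for population); binary formats common in
  the field are out of scope for this package's I/O layer.
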