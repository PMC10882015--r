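# heatrends

Percentile-based heatwave detection, annual heatwave indices, and
persistence-aware trend analysis for gridded daily temperature, with
population-exposure overlays. Built for climate-extremes and environmental
epidemiology work in low-variability (tropical) domains such as Peninsular
Malaysia, where absolute temperature thresholds are uninformative and
heatwaves must be defined relative to each grid cell's own climatology.

## What it computes

**Detection.** A heatwave at a grid cell is a maximal run of ≥ 3 consecutive
days with daily maximum temperature above that cell's 95th, 97.5th or 99th
percentile computed over a 1961–1990 reference period
(Tmax > q_p; a *day–night* mode additionally requires Tmin above its own
threshold). A separate classifier reproduces the Malaysian national
three-level alert scale for 3-day windows of Tmax
(level 1: min ∈ [35, 37) °C; level 2: [37, 40] °C; level 3: > 40 °C).

**Annual indices.** Per year and percentile: affected area AHW (km²,
spherical cell areas), maximum duration DHW (days), peak temperature THW
(°C), cumulative exceedance CTHW (°C·day), heatwave index
HWI = Σ_events (cell area ⁄ total land area), and the day–night
counterparts AHWN (% of land area), DHWN, THWN, CTHWN.

**Trends.** Sen's slope (median of all pairwise slopes) and the modified
Mann–Kendall test under the scaling hypothesis: the Hurst exponent H of the
Sen-detrended normal scores is estimated by maximum likelihood under the
fractional-Gaussian-noise autocorrelation
ρ_l = ½(|l+1|^{2H} − 2|l|^{2H} + |l−1|^{2H});
when H is significant against its white-noise null moments, the variance of
the MK statistic S is replaced by the scaled arcsine sum
Var(S)^H = Σ_{i<j} Σ_{k<l} (2/π) · asin((ρ_{|j−l|} − ρ_{|i−l|} − ρ_{|j−k|} +
ρ_{|i−k|}) ⁄ √((2 − 2ρ_{|i−j|})(2 − 2ρ_{|k−l|}))),
bias-corrected by the published empirical polynomial B(H, n), before forming
the continuity-corrected deviate Z and two-sided p-value.

**Exposure.** Fine population rasters are aggregated to the analysis grid by
fractional-area overlap (NA cells skipped), and the annual affected
population is the sum over cells hosting at least one event that year.

**Synthetic data.** A generator produces daily Tmax/Tmin cubes with a weak
tropical seasonal cycle, iid/AR(1)/exact-fGn anomalies, a secular trend,
injectable ground-truth heat events, and clustered population rasters — so
the full pipeline, including end-to-end event recovery, runs and is tested
entirely offline.

## Worked example

```r
library(heatrends)

cfg  <- synthetic_climate_config(n_years = 30, start_year = 1961,
                                 grid_shape = c(3, 3),
                                 noise_model = "ar1", ar1_phi = 0.6,
                                 trend_per_decade = 0.3, seed = 2024)
temp <- generate_daily_temperature(cfg)
pop  <- generate_population(synthetic_population_config(seed = 2024),
                            temp$grid, year = 1990)

res <- run_heatwave_pipeline(temp, pops = list(pop),
                             ref_period = c(1961, 1980),
                             exposure_years = 1990)
res
#> <heatwave_analysis>
#>   events:   1813 (1229 day / 584 day-night)
#>   years:    1961-1990
#>   trends:   27 index x percentile cells, 24 significant at alpha = 0.05

dplyr::select(dplyr::filter(res$indices, percentile == 95, year >= 1986),
              year, AHW, DHW, THW, HWI)
#> # A tibble: 5 × 5
#>    year   AHW   DHW   THW   HWI
#>   <int> <dbl> <int> <dbl> <dbl>
#> 1  1986 6952.    10  33.8  5.67
#> 2  1987 6952.    13  34.0  5.89
#> 3  1988 6952.    14  34.4  5.67
#> 4  1989 6952.    12  34.1  5.00
#> 5  1990 6952.    18  34.2  5.89

dplyr::filter(res$trends, index %in% c("AHW", "DHW", "HWI"),
              percentile == 95)
#> # A tibble: 3 × 8
#>   index percentile slope_per_decade  p_value significant     Z H_hat ltp_applied
#>   <chr>      <dbl>            <dbl>    <dbl> <lgl>       <dbl> <dbl> <lgl>
#> 1 AHW           95          1104.    1.39e-1 FALSE        1.48 0.802 TRUE
#> 2 DHW           95             2.86  3.10e-7 TRUE         5.12 0.500 FALSE
#> 3 HWI           95             2.02  1.51e-3 TRUE         3.17 0.604 TRUE
```

Reading the output: by the late 1980s every cell of the warming 3×3 domain
(6952 km² of land) hosts events each year, so AHW saturates while durations
keep growing (DHW trend +2.9 days/decade, p ≈ 3e-7). The AHW series itself
is strongly autocorrelated once saturated: the test estimates Ĥ ≈ 0.80,
applies the long-term-persistence correction (`ltp_applied = TRUE`), and —
honestly — declines to call the slope significant, whereas a classical MK
test on the same series would. `autoplot(res$indices)` and
`autoplot(res$exposure)` render the standard three-threshold time-series
panels; `tidy()`/`glance()` on any `mmk_test()` give broom-style one-row
summaries.

A thin command-line wrapper over the same functions ships in
`inst/cli/heatwaves.R` (`simulate | run | report`).

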