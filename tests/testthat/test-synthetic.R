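# Synthetic climate and population generators.

test_that("config invariants are enforced", {
  expect_error(synthetic_climate_config(tmax_annual_cycle = rep(20, 12)),
               "exceed")
  expect_error(synthetic_climate_config(noise_model = "ar1"), "ar1_phi")
  expect_error(synthetic_climate_config(noise_model = "fgn"), "hurst_H")
  expect_error(synthetic_climate_config(noise_model = "fgn", hurst_H = 0.4),
               "0.5")
  expect_error(synthetic_climate_config(ar1_phi = 0.5), "only applies")
})

test_that("same config and seed give bit-identical cubes", {
  cfg <- synthetic_climate_config(n_years = 2, grid_shape = c(2, 2),
                                  noise_model = "ar1", ar1_phi = 0.6,
                                  seed = 31)
  a <- generate_daily_temperature(cfg)
  b <- generate_daily_temperature(cfg)
  expect_identical(a$tmax, b$tmax)
  expect_identical(a$tmin, b$tmin)
})

test_that("noise-free cube reproduces the seasonal cycle anchors", {
  # step interpolation: every December day sits on the December mean
  cfg <- synthetic_climate_config(n_years = 1, grid_shape = c(2, 2),
                                  noise_sd = 0, trend_per_decade = 0,
                                  diurnal_offset_sd = 0,
                                  seasonal_interp = "step", seed = 1)
  temp <- generate_daily_temperature(cfg)
  dec <- temp$time$doy > 365 - 31
  expect_true(all(temp$tmax[dec, , ] == 28.1))
  expect_true(all(abs(temp$tmax[temp$time$doy %in% 91:120, , ] - 30.8)
                  < 1e-12))
  # linear interpolation: December *mean* stays close to the anchor and
  # April remains the warmest month
  cfg2 <- synthetic_climate_config(n_years = 1, grid_shape = c(1, 1),
                                   noise_sd = 0, trend_per_decade = 0,
                                   diurnal_offset_sd = 0,
                                   seasonal_interp = "linear", seed = 1)
  t2 <- generate_daily_temperature(cfg2)
  monthly <- tapply(t2$tmax[, 1, 1],
                    rep(1:12, times = heatrends:::.month_len), mean)
  expect_equal(unname(monthly[12]), 28.1, tolerance = 0.15)
  expect_equal(unname(which.max(monthly)), 4)
  expect_true(all(t2$tmax >= t2$tmin))
})

test_that("a pure trend ramp has the configured slope", {
  cfg <- synthetic_climate_config(n_years = 20, grid_shape = c(1, 1),
                                  noise_sd = 0, trend_per_decade = 0.5,
                                  diurnal_offset_sd = 0, seed = 1)
  temp <- generate_daily_temperature(cfg)
  annual <- tapply(temp$tmax[, 1, 1], temp$time$year, mean)
  fit <- stats::lm(annual ~ seq_along(annual))
  expect_equal(unname(stats::coef(fit)[2]), 0.05, tolerance = 1e-6)
})

test_that("AR(1) anomalies carry the configured lag-1 autocorrelation", {
  cfg <- synthetic_climate_config(n_years = 50, grid_shape = c(1, 1),
                                  noise_model = "ar1", ar1_phi = 0.6,
                                  trend_per_decade = 0,
                                  diurnal_offset_sd = 0, seed = 17)
  temp <- generate_daily_temperature(cfg)
  cyc <- rep(heatrends:::seasonal_cycle_365(cfg$tmax_annual_cycle, "linear"),
             50)
  anom <- temp$tmax[, 1, 1] - cyc
  r1 <- stats::acf(anom, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(r1, 0.6, tolerance = 0.05)
  # marginal sd close to noise_sd
  expect_equal(stats::sd(anom), cfg$noise_sd, tolerance = 0.05)
})

# Sample second moments of strong long-memory series converge at rate
# n^(2H-2), so the single-realisation check is restricted to H <= 0.8
# and the H = 0.9 check averages independent realisations. The sample
# autocovariance is taken about the process's true (zero) mean; the
# demeaned acf() is biased low by exactly the variance of the sample
# mean, which is O(n^(2H-2)) and not a generator defect.
zero_mean_acf <- function(x, lags) {
  n <- length(x)
  sapply(lags, function(l) mean(x[1:(n - l)] * x[(1 + l):n]))
}

test_that("fGn sample autocorrelation matches the closed form", {
  for (H in c(0.6, 0.7, 0.8)) {
    x <- as.numeric(generate_fgn(10000, H, 1, seed = 1000 + round(100 * H)))
    dev <- zero_mean_acf(x, 1:5) - fgn_autocorrelation(1:5, H)
    expect_lt(max(abs(dev)), 0.05, label = paste("H =", H))
  }
  withr::local_seed(1090)
  acc <- rowMeans(replicate(50, {
    zero_mean_acf(as.numeric(generate_fgn(5000, 0.9, 1)), 1:5)
  }))
  expect_lt(max(abs(acc - fgn_autocorrelation(1:5, 0.9))), 0.05)
})

test_that("fGn generation is deterministic and reports its method", {
  a <- generate_fgn(512, 0.8, 2, seed = 4)
  b <- generate_fgn(512, 0.8, 2, seed = 4)
  expect_identical(a, b)
  expect_true(attr(a, "method") %in% c("circulant", "cholesky"))
  expect_equal(stats::sd(a), 2, tolerance = 0.3)
})

test_that("event injection is exact bookkeeping", {
  temp <- flat_cube(n_years = 1)
  # empty list: identical output
  same <- inject_heatwaves(temp, injected_events(integer(), integer(),
                                                 integer(), integer(),
                                                 integer(), numeric()))
  expect_identical(same$tmax, temp$tmax)
  # one 5-day event changes exactly 5 cell-days
  ev <- injected_events(1L, 2L, 1961L, 100L, 5L, amplitude = 10)
  mod <- inject_heatwaves(temp, ev)
  expect_equal(sum(mod$tmax != temp$tmax), 5)
  expect_equal(mod$tmax[100:104, 1, 2], rep(40, 5))
  expect_identical(attr(mod, "ground_truth")$duration, 5L)
  # out-of-range events are rejected with the index named
  bad <- injected_events(1L, 2L, 1961L, 364L, 5L, amplitude = 10)
  expect_error(inject_heatwaves(temp, bad), "event 1")
  bad2 <- injected_events(9L, 1L, 1961L, 10L, 3L, amplitude = 1)
  expect_error(inject_heatwaves(temp, bad2), "outside")
})

test_that("population generator honours totals, NA fraction, nesting", {
  grid <- grid_definition(c(1.125, 1.375), c(100.125, 100.375), 0.25)
  cfg <- synthetic_population_config(fine_factor = 3, na_fraction = 0,
                                     total_population = 1000, seed = 2)
  pop <- generate_population(cfg, grid, 2000)
  expect_equal(sum(pop$counts), 1000)
  expect_true(all(pop$counts >= 0))
  expect_equal(dim(pop$counts), c(6, 6))
  # fine_factor = 1 reproduces the coarse geometry
  pop1 <- generate_population(
    synthetic_population_config(fine_factor = 1, na_fraction = 0, seed = 2),
    grid, 2000)
  expect_equal(pop1$grid$lat, grid$lat)
  # determinism
  again <- generate_population(cfg, grid, 2000)
  expect_identical(pop$counts, again$counts)
  # NA fraction materialises and non-NA counts still sum to the total
  cfg_na <- synthetic_population_config(fine_factor = 5, na_fraction = 0.2,
                                        total_population = 5000, seed = 3)
  pop_na <- generate_population(cfg_na, grid, 2000)
  expect_gt(sum(is.na(pop_na$counts)), 0)
  expect_equal(sum(pop_na$counts, na.rm = TRUE), 5000)
})
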