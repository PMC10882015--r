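# Thresholds, run extraction, event extraction, alert classification.

test_that("thresholds of a constant series equal the constant", {
  temp <- flat_cube(n_years = 2, tmax = 30, tmin = 22)
  thr <- compute_thresholds(temp, c(1961, 1962))
  expect_true(all(thr$tmax_thresholds == 30))
  expect_true(all(thr$tmin_thresholds == 22))
})

test_that("pooled quantiles interpolate order statistics linearly", {
  # 100 reference days valued 1..100: the 95th percentile under linear
  # interpolation of order statistics is 95.05
  g <- grid_definition(1, 100, 0.25)
  vals <- c(1:100, rep(NA_real_, 265))
  temp <- grid_daily_temperature(
    g, heatrends:::noleap_time_table(1961, 1),
    array(vals, c(365, 1, 1)), array(vals - 10, c(365, 1, 1)))
  thr <- compute_thresholds(temp, c(1961, 1961), percentiles = 95,
                            max_missing_fraction = 0.8)
  manual <- {
    o <- sort(1:100)
    h <- (100 - 1) * 0.95 + 1
    o[floor(h)] + (h - floor(h)) * (o[floor(h) + 1] - o[floor(h)])
  }
  expect_equal(thr$tmax_thresholds[1, 1, 1], manual)
  expect_equal(manual, 95.05)
})

test_that("thresholds are monotone in percentile and NA when data too gappy", {
  withr::local_seed(12)
  g <- grid_definition(c(1, 1.25), 100, 0.25)
  vals <- array(rnorm(730 * 2, 30, 2), c(730, 2, 1))
  vals[1:200, 2, 1] <- NA  # 27% missing in cell 2
  temp <- grid_daily_temperature(
    g, heatrends:::noleap_time_table(1961, 2), vals, vals - 8)
  thr <- compute_thresholds(temp, c(1961, 1962))
  t1 <- thr$tmax_thresholds[1, 1, ]
  expect_true(all(diff(t1) >= 0))
  expect_true(all(is.na(thr$tmax_thresholds[2, 1, ])))
  expect_error(compute_thresholds(temp, c(1950, 1962)), "outside")
})

test_that("detect_runs handles the boundary cases", {
  expect_equal(detect_runs(c(TRUE, TRUE, TRUE, FALSE))$start, 1L)
  expect_equal(detect_runs(c(TRUE, TRUE, TRUE, FALSE))$length, 3L)
  expect_equal(nrow(detect_runs(c(TRUE, TRUE, FALSE, TRUE, TRUE))), 0)
  # missing days break runs
  expect_equal(nrow(detect_runs(c(TRUE, TRUE, NA, TRUE, TRUE))), 0)
  expect_equal(detect_runs(rep(TRUE, 4), min_len = 1),
               tibble::tibble(start = 1L, length = 4L))
  expect_error(detect_runs(TRUE, min_len = 0), "min_len")
})

test_that("detect_runs equals exhaustive scanning on all 4096 length-12 masks", {
  for (code in 0:4095) {
    mask <- as.logical(bitwAnd(code, 2^(0:11)) > 0)
    expect_identical(detect_runs(mask, 3), scan_runs(mask, 3))
  }
})

test_that("extract_events recovers an injected block with its statistics", {
  temp <- flat_cube(n_years = 2, tmax = 30, tmin = 22)
  # raise one cell 10 degC for 5 days in year 2
  temp$tmax[400:404, 1, 1] <- 40
  temp$tmin[400:404, 1, 1] <- 32
  thr <- compute_thresholds(temp, c(1961, 1961))  # quiet reference year
  ev <- extract_events(temp, thr, 95, mode = "day")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cell_lat_idx, 1L)
  expect_equal(ev$year, 1962L)
  expect_equal(ev$start_doy, 35L)
  expect_equal(ev$duration, 5L)
  expect_equal(ev$peak_tmax, 40)
  expect_equal(ev$cumulative_exceedance, 5 * (40 - 30))
  # day-night mode agrees here since tmin was raised too
  evn <- extract_events(temp, thr, 95, mode = "day_night")
  expect_equal(nrow(evn), 1)
  expect_equal(evn$mode, "day_night")
})

test_that("event statistics match a per-event recomputation oracle", {
  withr::local_seed(99)
  cfg <- synthetic_climate_config(n_years = 8, start_year = 1961,
                                  grid_shape = c(2, 2), noise_sd = 1.5,
                                  seed = 99)
  temp <- generate_daily_temperature(cfg)
  thr <- compute_thresholds(temp, c(1961, 1966))
  ev <- extract_events(temp, thr, 95, mode = "day")
  expect_gt(nrow(ev), 5)
  p_idx <- match(95, thr$percentiles)
  day0 <- cumsum(c(0, rep(365, 7)))
  for (r in seq_len(nrow(ev))) {
    e <- ev[r, ]
    t0 <- day0[e$year - 1960] + e$start_doy
    span <- t0:(t0 + e$duration - 1)
    tx <- temp$tmax[span, e$cell_lat_idx, e$cell_lon_idx]
    th <- thr$tmax_thresholds[e$cell_lat_idx, e$cell_lon_idx, p_idx]
    expect_true(all(tx > th))
    expect_equal(e$peak_tmax, max(tx))
    expect_equal(e$cumulative_exceedance, sum(tx - th))
    # maximality: neighbours fail the run condition
    if (t0 > 1) expect_false(temp$tmax[t0 - 1, e$cell_lat_idx,
                                       e$cell_lon_idx] > th)
    t_end <- t0 + e$duration - 1
    if (t_end < 8 * 365) expect_false(temp$tmax[t_end + 1, e$cell_lat_idx,
                                                e$cell_lon_idx] > th)
  }
})

test_that("higher-percentile events nest inside lower-percentile events", {
  cfg <- synthetic_climate_config(n_years = 10, start_year = 1961,
                                  grid_shape = c(2, 2), noise_model = "ar1",
                                  ar1_phi = 0.7, noise_sd = 1.2, seed = 55)
  temp <- generate_daily_temperature(cfg)
  thr <- compute_thresholds(temp, c(1961, 1968))
  ev95 <- extract_events(temp, thr, 95, "day")
  ev99 <- extract_events(temp, thr, 99, "day")
  day0 <- function(e) (e$year - 1961) * 365 + e$start_doy
  for (r in seq_len(nrow(ev99))) {
    e <- ev99[r, ]
    host <- dplyr::filter(ev95, .data$cell_lat_idx == e$cell_lat_idx,
                          .data$cell_lon_idx == e$cell_lon_idx)
    s99 <- day0(e)
    contained <- any(day0(host) <= s99 &
                       day0(host) + host$duration >= s99 + e$duration)
    expect_true(contained)
  }
  # day-night events are a subset of day events (same percentile)
  evdn <- extract_events(temp, thr, 95, "day_night")
  if (nrow(evdn) > 0) {
    for (r in seq_len(nrow(evdn))) {
      e <- evdn[r, ]
      host <- dplyr::filter(ev95, .data$cell_lat_idx == e$cell_lat_idx,
                            .data$cell_lon_idx == e$cell_lon_idx)
      expect_true(any(day0(host) <= day0(e) &
                        day0(host) + host$duration >= day0(e) + e$duration))
    }
  }
})

test_that("end-to-end recovery of injected events is exact", {
  fx <- recovery_fixture()
  thr <- compute_thresholds(fx$temp, fx$ref)
  ev <- extract_events(fx$temp, thr, 99, "day")
  got <- dplyr::arrange(
    dplyr::select(tibble::as_tibble(ev), "cell_lat_idx", "cell_lon_idx",
                  year = "year", start_doy = "start_doy",
                  duration = "duration"),
    .data$cell_lat_idx)
  want <- dplyr::arrange(
    dplyr::select(tibble::as_tibble(fx$truth), "cell_lat_idx",
                  "cell_lon_idx", year = "start_year",
                  start_doy = "start_doy", duration = "duration"),
    .data$cell_lat_idx)
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
})

test_that("Malaysian alert levels reproduce the national bands", {
  expect_identical(classify_malaysian_level(c(36, 36, 36)), 1L)
  expect_identical(classify_malaysian_level(c(41, 41.5, 40.1)), 3L)
  expect_identical(classify_malaysian_level(c(34.9, 36, 36)), 0L)
  expect_identical(classify_malaysian_level(c(37, 39.9, 38)), 2L)
  expect_identical(classify_malaysian_level(c(40, 40, 40)), 2L)
  expect_identical(classify_malaysian_level(c(35, 35, 35)), 1L)
  expect_error(classify_malaysian_level(c(36, 36)), "exactly 3")
  expect_warning(lv <- classify_malaysian_level(c(36, NA, 36)), "missing")
  expect_identical(lv, 0L)
})
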