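# Shared fixture builders: tiny cubes with hand-set values, so tests can
# state expectations in plain numbers.

# A cube with constant background temperature on a small grid.
flat_cube <- function(n_years = 2, start_year = 1961, nlat = 2, nlon = 2,
                      tmax = 30, tmin = 22, lat0 = 0, cell = 0.25) {
  g <- grid_definition(lat0 + (seq_len(nlat) - 1) * cell,
                       100 + (seq_len(nlon) - 1) * cell, cell)
  nt <- n_years * 365L
  grid_daily_temperature(
    g, heatrends:::noleap_time_table(start_year, n_years),
    array(tmax, c(nt, nlat, nlon)), array(tmin, c(nt, nlat, nlon))
  )
}

# Exhaustive run-finder used as the oracle for detect_runs.
scan_runs <- function(mask, min_len) {
  mask <- !is.na(mask) & mask
  n <- length(mask)
  out <- list()
  i <- 1
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) out[[length(out) + 1]] <- c(i, j - i + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    tibble::tibble(start = integer(), length = integer())
  } else {
    m <- do.call(rbind, out)
    tibble::tibble(start = as.integer(m[, 1]), length = as.integer(m[, 2]))
  }
}

# Study-conditions cube for end-to-end recovery: quiet iid background
# (sd 0.5 degC, no trend) with injected 8-degC events on a 2x2 grid,
# 1961-1976 with a 1961-1975 reference window. Kept deliberately small:
# every background cell-day has a 1% chance of exceeding its 99th
# percentile threshold, so the probability of a spontaneous 3-day
# background run grows with cube volume and would confound the
# recovered-set comparison on a large cube.
recovery_fixture <- function(seed = 42) {
  cfg <- synthetic_climate_config(
    n_years = 16, start_year = 1961, grid_shape = c(2, 2),
    noise_model = "iid", noise_sd = 0.5, trend_per_decade = 0,
    diurnal_offset_sd = 0.2, seed = seed)
  truth <- injected_events(
    cell_lat_idx = c(1L, 2L), cell_lon_idx = c(1L, 2L),
    start_year = c(1976L, 1976L), start_doy = c(100L, 250L),
    duration = c(5L, 3L), amplitude = 8)
  temp <- inject_heatwaves(generate_daily_temperature(cfg), truth)
  list(temp = temp, truth = truth, ref = c(1961, 1975))
}
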