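# Synthetic study inputs: daily Tmax/Tmin cubes with a weak tropical
# seasonal cycle, serially correlated anomalies (iid / AR(1) / fGn), a
# secular warming trend, injectable multi-day heat events with a ground
# truth ledger, and clustered fine-resolution population rasters. These
# emulate the statistical structure of a reanalysis temperature cube over
# a humid tropical peninsula and of a ~1-km population count raster, so
# the whole pipeline is testable without any download.

# Monthly-mean anchors for a humid tropical peninsula: Tmax lowest in
# December (28.1 degC) and highest in April (30.8); Tmin lowest in
# January (21.8) and highest in May (23.3). Intermediate months follow a
# smooth annual cycle through those anchors.
.default_tmax_cycle <- c(28.6, 29.4, 30.3, 30.8, 30.6, 30.3,
                         30.0, 29.9, 29.8, 29.5, 28.9, 28.1)
.default_tmin_cycle <- c(21.8, 22.1, 22.6, 23.0, 23.3, 23.2,
                         22.9, 22.9, 22.9, 22.9, 22.5, 22.0)

#' Configuration for the synthetic daily-temperature generator
#'
#' @param n_years Number of simulated years (365-day no-leap calendar).
#' @param start_year First calendar year label.
#' @param grid_shape Integer `(n_lat, n_lon)`.
#' @param cell_size_deg Cell size in degrees.
#' @param lat0,lon0 Grid origin (center of the south-west cell), degrees.
#' @param tmax_annual_cycle,tmin_annual_cycle 12 monthly means, degrees
#'   Celsius; every Tmax mean must strictly exceed the Tmin mean.
#' @param noise_model `"iid"`, `"ar1"` or `"fgn"` daily anomalies.
#' @param ar1_phi AR(1) coefficient in (-1, 1); required iff
#'   `noise_model = "ar1"`.
#' @param hurst_H Hurst exponent in (0.5, 1); required iff
#'   `noise_model = "fgn"`.
#' @param noise_sd Marginal anomaly standard deviation, degrees Celsius.
#' @param trend_per_decade Secular warming trend added linearly in time,
#'   degrees Celsius per decade.
#' @param diurnal_offset_sd Standard deviation of the independent Tmin
#'   offset, degrees Celsius.
#' @param lat_gradient Deterministic gradient in degrees Celsius per
#'   degree latitude (0 disables; see the vignette).
#' @param seasonal_interp `"linear"`: periodic linear interpolation of the
#'   monthly means to day-of-year at month midpoints; `"step"`: constant
#'   within each month.
#' @param land_mask Optional logical `n_lat x n_lon` mask.
#' @param seed Integer seed; same config + seed gives bit-identical output.
#' @return Object of class `synthetic_climate_config`.
#' @export
synthetic_climate_config <- function(n_years = 73,
                                     start_year = 1950,
                                     grid_shape = c(4, 4),
                                     cell_size_deg = 0.25,
                                     lat0 = 1.375, lon0 = 99.375,
                                     tmax_annual_cycle = .default_tmax_cycle,
                                     tmin_annual_cycle = .default_tmin_cycle,
                                     noise_model = c("iid", "ar1", "fgn"),
                                     ar1_phi = NULL,
                                     hurst_H = NULL,
                                     noise_sd = 0.8,
                                     trend_per_decade = 0.18,
                                     diurnal_offset_sd = 0.3,
                                     lat_gradient = 0,
                                     seasonal_interp = c("linear", "step"),
                                     land_mask = NULL,
                                     seed = 1L) {
  noise_model <- match.arg(noise_model)
  seasonal_interp <- match.arg(seasonal_interp)
  if (length(tmax_annual_cycle) != 12 || length(tmin_annual_cycle) != 12) {
    stop("annual cycles must have 12 monthly means", call. = FALSE)
  }
  if (!all(tmax_annual_cycle > tmin_annual_cycle)) {
    stop("every monthly Tmax mean must exceed the Tmin mean", call. = FALSE)
  }
  if (noise_model == "ar1") {
    if (is.null(ar1_phi)) stop("ar1_phi required for noise_model 'ar1'",
                               call. = FALSE)
    if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)", call. = FALSE)
  } else if (!is.null(ar1_phi)) {
    stop("ar1_phi only applies to noise_model 'ar1'", call. = FALSE)
  }
  if (noise_model == "fgn") {
    if (is.null(hurst_H)) stop("hurst_H required for noise_model 'fgn'",
                               call. = FALSE)
    if (hurst_H <= 0.5 || hurst_H >= 1) {
      stop("hurst_H must lie in (0.5, 1)", call. = FALSE)
    }
  } else if (!is.null(hurst_H)) {
    stop("hurst_H only applies to noise_model 'fgn'", call. = FALSE)
  }
  if (noise_sd < 0 || diurnal_offset_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  structure(
    list(n_years = as.integer(n_years), start_year = as.integer(start_year),
         grid_shape = as.integer(grid_shape),
         cell_size_deg = cell_size_deg, lat0 = lat0, lon0 = lon0,
         tmax_annual_cycle = tmax_annual_cycle,
         tmin_annual_cycle = tmin_annual_cycle,
         noise_model = noise_model, ar1_phi = ar1_phi, hurst_H = hurst_H,
         noise_sd = noise_sd, trend_per_decade = trend_per_decade,
         diurnal_offset_sd = diurnal_offset_sd,
         lat_gradient = lat_gradient, seasonal_interp = seasonal_interp,
         land_mask = land_mask, seed = as.integer(seed)),
    class = "synthetic_climate_config"
  )
}

# Month lengths and midpoints of a 365-day year.
.month_len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Map 12 monthly means onto 365 days of year
#' @param monthly 12 values.
#' @param method `"linear"` periodic interpolation at month midpoints, or
#'   `"step"` monthly plateaus.
#' @return Numeric vector of length 365.
#' @keywords internal
seasonal_cycle_365 <- function(monthly, method = c("linear", "step")) {
  method <- match.arg(method)
  if (method == "step") {
    return(rep(monthly, times = .month_len))
  }
  mid <- cumsum(.month_len) - .month_len / 2 + 0.5
  x <- c(mid[12] - 365, mid, mid[1] + 365)
  y <- c(monthly[12], monthly, monthly[1])
  stats::approx(x, y, xout = 1:365)$y
}

#' Generate a synthetic gridded daily temperature cube
#'
#' Builds `Tmax = seasonal cycle + latitudinal gradient + anomaly + trend`
#' per cell-day, with `Tmin` sharing the anomaly plus an independent
#' diurnal offset and clipped so that `Tmax >= Tmin` everywhere. Anomaly
#' series are independent across cells and follow the configured noise
#' model (iid, AR(1), or exact fGn).
#'
#' @param cfg A [synthetic_climate_config()].
#' @return A [grid_daily_temperature()] on a 365-day no-leap calendar.
#' @examples
#' temp <- generate_daily_temperature(
#'   synthetic_climate_config(n_years = 2, grid_shape = c(2, 2), seed = 7))
#' temp
#' @export
generate_daily_temperature <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_climate_config"))
  local_seed(cfg$seed)
  nlat <- cfg$grid_shape[1]; nlon <- cfg$grid_shape[2]
  lat <- cfg$lat0 + (seq_len(nlat) - 1) * cfg$cell_size_deg
  lon <- cfg$lon0 + (seq_len(nlon) - 1) * cfg$cell_size_deg
  grid <- grid_definition(lat, lon, cfg$cell_size_deg, cfg$land_mask)
  nt <- cfg$n_years * 365L
  time <- noleap_time_table(cfg$start_year, cfg$n_years)
  cyc_max <- rep(seasonal_cycle_365(cfg$tmax_annual_cycle,
                                    cfg$seasonal_interp), cfg$n_years)
  cyc_min <- rep(seasonal_cycle_365(cfg$tmin_annual_cycle,
                                    cfg$seasonal_interp), cfg$n_years)
  trend <- cfg$trend_per_decade / 10 * (seq_len(nt) - 1) / 365
  grad <- cfg$lat_gradient * (lat - mean(lat))
  tmax <- array(NA_real_, c(nt, nlat, nlon))
  tmin <- tmax
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      anom <- draw_anomalies(nt, cfg)
      off <- if (cfg$diurnal_offset_sd > 0) {
        stats::rnorm(nt, sd = cfg$diurnal_offset_sd)
      } else {
        numeric(nt)
      }
      tx <- cyc_max + grad[i] + anom + trend
      tn <- cyc_min + grad[i] + anom + off + trend
      tmax[, i, j] <- tx
      tmin[, i, j] <- pmin(tn, tx)
    }
  }
  grid_daily_temperature(grid, time, tmax, tmin, calendar = "noleap")
}

draw_anomalies <- function(nt, cfg) {
  if (cfg$noise_sd == 0) return(numeric(nt))
  switch(cfg$noise_model,
    iid = stats::rnorm(nt, sd = cfg$noise_sd),
    ar1 = {
      phi <- cfg$ar1_phi
      innov_sd <- cfg$noise_sd * sqrt(1 - phi^2)
      as.numeric(stats::arima.sim(list(ar = phi), nt, sd = innov_sd,
                                  n.start = 500))
    },
    fgn = as.numeric(generate_fgn(nt, cfg$hurst_H, cfg$noise_sd))
  )
}

#' Specify heat events to inject into a synthetic cube
#'
#' @param cell_lat_idx,cell_lon_idx 1-based cell indices (vectorised; one
#'   event per element).
#' @param start_year,start_doy Event start (year label and day of year).
#' @param duration Event length in days, `>= 1`.
#' @param amplitude Degrees Celsius added to Tmax on event days.
#' @param amplitude_tmin Degrees Celsius added to Tmin (default: same as
#'   `amplitude`, so day-night detection also fires).
#' @return Tibble of class `injected_event_spec`, one row per event.
#' @export
injected_events <- function(cell_lat_idx, cell_lon_idx, start_year,
                            start_doy, duration, amplitude,
                            amplitude_tmin = amplitude) {
  ev <- tibble::tibble(
    cell_lat_idx = as.integer(cell_lat_idx),
    cell_lon_idx = as.integer(cell_lon_idx),
    start_year = as.integer(start_year),
    start_doy = as.integer(start_doy),
    duration = as.integer(duration),
    amplitude = as.numeric(amplitude),
    amplitude_tmin = as.numeric(amplitude_tmin)
  )
  if (any(ev$duration < 1)) stop("duration must be >= 1", call. = FALSE)
  class(ev) <- c("injected_event_spec", class(ev))
  ev
}

#' Inject multi-day heat events into a temperature cube
#'
#' Adds each event's amplitude to Tmax (and `amplitude_tmin` to Tmin) on
#' the specified consecutive cell-days; all other values are untouched.
#' The returned cube carries the ground-truth ledger as attribute
#' `"ground_truth"` for recovery checks.
#'
#' @param temp A [grid_daily_temperature()].
#' @param events An [injected_events()] table (zero rows allowed).
#' @return Modified copy of `temp`.
#' @export
inject_heatwaves <- function(temp, events) {
  stopifnot(inherits(temp, "grid_daily_temperature"))
  events <- tibble::as_tibble(events)
  nt <- nrow(temp$time)
  nlat <- length(temp$grid$lat); nlon <- length(temp$grid$lon)
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    t0 <- match(TRUE, temp$time$year == e$start_year &
                  temp$time$doy == e$start_doy)
    idx <- t0 + seq_len(e$duration) - 1L
    if (is.na(t0) || max(idx) > nt ||
        e$cell_lat_idx < 1 || e$cell_lat_idx > nlat ||
        e$cell_lon_idx < 1 || e$cell_lon_idx > nlon) {
      stop("injected event ", k, " lies outside the simulated grid/period",
           call. = FALSE)
    }
    temp$tmax[idx, e$cell_lat_idx, e$cell_lon_idx] <-
      temp$tmax[idx, e$cell_lat_idx, e$cell_lon_idx] + e$amplitude
    temp$tmin[idx, e$cell_lat_idx, e$cell_lon_idx] <-
      temp$tmin[idx, e$cell_lat_idx, e$cell_lon_idx] + e$amplitude_tmin
  }
  attr(temp, "ground_truth") <- events
  temp
}

#' Configuration for the synthetic population raster
#'
#' @param fine_factor Integer subdivision of each temperature cell per
#'   axis (30-arcsecond-style rasters sit ~30x finer than a quarter-degree
#'   grid).
#' @param n_clusters Number of Gaussian population clusters (cities).
#' @param total_population Total person count to distribute.
#' @param na_fraction Fraction of fine cells set to `NA` (nodata), in
#'   `[0, 1)`.
#' @param cluster_sd_cells Cluster spread in fine-cell units.
#' @param seed Integer seed.
#' @return Object of class `synthetic_population_config`.
#' @export
synthetic_population_config <- function(fine_factor = 5, n_clusters = 3,
                                        total_population = 1e6,
                                        na_fraction = 0.05,
                                        cluster_sd_cells = 2,
                                        seed = 1L) {
  if (fine_factor < 1) stop("fine_factor must be >= 1", call. = FALSE)
  if (na_fraction < 0 || na_fraction >= 1) {
    stop("na_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(fine_factor = as.integer(fine_factor),
         n_clusters = as.integer(n_clusters),
         total_population = total_population,
         na_fraction = na_fraction,
         cluster_sd_cells = cluster_sd_cells,
         seed = as.integer(seed)),
    class = "synthetic_population_config"
  )
}

#' Generate a clustered synthetic population raster
#'
#' Subdivides each cell of `grid` by `fine_factor`, draws cluster centers
#' uniformly over the fine grid, weights fine cells by a Gaussian mixture
#' around those centers, marks `na_fraction` of cells as nodata, and
#' multinomially allocates `total_population` persons over the non-NA
#' cells (so non-NA counts sum exactly to the total).
#'
#' @param cfg A [synthetic_population_config()].
#' @param grid Target (temperature) [grid_definition()].
#' @param year Year stamp for the raster.
#' @return A fine-resolution [population_grid()].
#' @export
generate_population <- function(cfg, grid, year = 2000L) {
  stopifnot(inherits(cfg, "synthetic_population_config"),
            inherits(grid, "grid_definition"))
  local_seed(cfg$seed)
  f <- cfg$fine_factor
  cs <- grid$cell_size / f
  nlat <- length(grid$lat) * f
  nlon <- length(grid$lon) * f
  lat <- (min(grid$lat) - grid$cell_size / 2) + (seq_len(nlat) - 0.5) * cs
  lon <- (min(grid$lon) - grid$cell_size / 2) + (seq_len(nlon) - 0.5) * cs
  fine_grid <- grid_definition(lat, lon, cs)
  ci <- stats::runif(cfg$n_clusters, 0.5, nlat + 0.5)
  cj <- stats::runif(cfg$n_clusters, 0.5, nlon + 0.5)
  ii <- matrix(seq_len(nlat), nlat, nlon)
  jj <- matrix(seq_len(nlon), nlat, nlon, byrow = TRUE)
  w <- matrix(0, nlat, nlon)
  for (k in seq_len(cfg$n_clusters)) {
    w <- w + exp(-((ii - ci[k])^2 + (jj - cj[k])^2) /
                   (2 * cfg$cluster_sd_cells^2))
  }
  w <- w + 1e-6  # rural floor: every cell can host people
  na_cells <- stats::runif(nlat * nlon) < cfg$na_fraction
  w[na_cells] <- 0
  counts <- numeric(nlat * nlon)
  counts[!na_cells] <- as.numeric(
    stats::rmultinom(1, size = cfg$total_population,
                     prob = as.numeric(w)[!na_cells]))
  counts[na_cells] <- NA_real_
  population_grid(fine_grid, matrix(counts, nlat, nlon), year)
}
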