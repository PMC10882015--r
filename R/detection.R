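# Heatwave detection: reference-period percentile thresholds per cell,
# run extraction (>= 3 consecutive exceedance days), day and day-night
# modes, and the Malaysian three-level alert classification.

#' Compute reference-period percentile thresholds per grid cell
#'
#' Thresholds are empirical quantiles of all daily values in the
#' reference window, pooled across the calendar (the seasonal range of a
#' humid tropical domain is small, so no day-of-year window is applied by
#' default; `pool = "doy_window"` restricts to a centred window per day
#' of year). Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Cells whose reference window has more than
#' `max_missing_fraction` missing days get `NA` thresholds and are
#' skipped downstream.
#'
#' @param temp A [grid_daily_temperature()].
#' @param ref_years `c(start_year, end_year)` reference window, inside the
#'   data period.
#' @param percentiles Numeric percentiles in (0, 100), default
#'   `c(95, 97.5, 99)`.
#' @param max_missing_fraction Maximum tolerated fraction of missing
#'   reference days per cell (default 0.1).
#' @param pool `"pooled"` (default) or `"doy_window"`.
#' @param doy_halfwidth Half-width in days of the day-of-year window when
#'   `pool = "doy_window"`.
#' @return Object of class `threshold_field` with arrays
#'   `tmax_thresholds` and `tmin_thresholds` (`n_lat x n_lon x n_pct`; for
#'   `doy_window`, `365 x n_lat x n_lon x n_pct`).
#' @export
compute_thresholds <- function(temp, ref_years,
                               percentiles = c(95, 97.5, 99),
                               max_missing_fraction = 0.1,
                               pool = c("pooled", "doy_window"),
                               doy_halfwidth = 15L) {
  stopifnot(inherits(temp, "grid_daily_temperature"))
  pool <- match.arg(pool)
  percentiles <- sort(as.numeric(percentiles))
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie in (0, 100)", call. = FALSE)
  }
  if (ref_years[1] < min(temp$time$year) || ref_years[2] > max(temp$time$year)) {
    stop("reference window ", ref_years[1], "-", ref_years[2],
         " lies outside the data period", call. = FALSE)
  }
  in_ref <- temp$time$year >= ref_years[1] & temp$time$year <= ref_years[2]
  nlat <- length(temp$grid$lat); nlon <- length(temp$grid$lon)
  np <- length(percentiles)
  q_or_na <- function(x) {
    if (mean(is.na(x)) > max_missing_fraction) {
      rep(NA_real_, np)
    } else {
      stats::quantile(x, percentiles / 100, na.rm = TRUE, names = FALSE,
                      type = 7)
    }
  }
  if (pool == "pooled") {
    thr_max <- array(NA_real_, c(nlat, nlon, np))
    thr_min <- thr_max
    for (i in seq_len(nlat)) {
      for (j in seq_len(nlon)) {
        thr_max[i, j, ] <- q_or_na(temp$tmax[in_ref, i, j])
        thr_min[i, j, ] <- q_or_na(temp$tmin[in_ref, i, j])
      }
    }
  } else {
    doy_ref <- temp$time$doy[in_ref]
    thr_max <- array(NA_real_, c(365, nlat, nlon, np))
    thr_min <- thr_max
    for (d in 1:365) {
      dd <- (abs(doy_ref - d) <= doy_halfwidth) |
        (365 - abs(doy_ref - d) <= doy_halfwidth)
      for (i in seq_len(nlat)) {
        for (j in seq_len(nlon)) {
          thr_max[d, i, j, ] <- q_or_na(temp$tmax[in_ref, i, j][dd])
          thr_min[d, i, j, ] <- q_or_na(temp$tmin[in_ref, i, j][dd])
        }
      }
    }
  }
  structure(
    list(grid = temp$grid, percentiles = percentiles,
         tmax_thresholds = thr_max, tmin_thresholds = thr_min,
         reference_period = as.integer(ref_years), pool = pool),
    class = "threshold_field"
  )
}

#' @export
print.threshold_field <- function(x, ...) {
  cat("<threshold_field> percentiles ",
      paste(x$percentiles, collapse = "/"), " over ",
      x$reference_period[1], "-", x$reference_period[2],
      " (", x$pool, ")\n", sep = "")
  invisible(x)
}

#' Find maximal runs of TRUE of a minimum length
#'
#' Missing values break runs (an `NA` day can never belong to a
#' heatwave). Returns maximal runs only: the elements immediately before
#' and after each reported run are not `TRUE`.
#'
#' @param exceed Logical vector (daily exceedance mask); `NA` treated as
#'   `FALSE`.
#' @param min_len Minimum run length in days (default 3).
#' @return Tibble with 1-based `start` and `length`, in order.
#' @examples
#' detect_runs(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
#' @export
detect_runs <- function(exceed, min_len = 3L) {
  if (min_len < 1) stop("min_len must be >= 1", call. = FALSE)
  exceed <- !is.na(exceed) & exceed
  r <- rle(exceed)
  len <- r$lengths
  ends <- cumsum(len)
  keep <- r$values & len >= min_len
  tibble::tibble(start = (ends - len + 1L)[keep], length = len[keep])
}

threshold_at <- function(thr, which = c("tmax", "tmin"), i, j, p_idx, doy) {
  a <- if (match.arg(which) == "tmax") thr$tmax_thresholds else thr$tmin_thresholds
  if (thr$pool == "pooled") rep(a[i, j, p_idx], length(doy)) else a[cbind(doy, i, j, p_idx)]
}

#' Extract heatwave events from a temperature cube
#'
#' Per-cell daily exceedance masks (day mode: `Tmax > threshold`;
#' day-night mode: `Tmax > its threshold` and `Tmin > its threshold` on
#' the same day) are reduced to maximal runs of at least `min_len` days.
#' Each run becomes one event with its peak Tmax and cumulative
#' exceedance `sum(Tmax - threshold)` over event days. Events are
#' attributed to the year containing their start day. Cells with
#' undefined thresholds are skipped (count reported via attribute
#' `"skipped_cells"`).
#'
#' @param temp A [grid_daily_temperature()].
#' @param thresholds A [compute_thresholds()] result on the same grid.
#' @param percentile One of the threshold field's percentiles.
#' @param mode `"day"` or `"day_night"`.
#' @param min_len Minimum run length (default 3 days).
#' @return Tibble of class `heatwave_events`: one row per event with
#'   columns `cell_lat_idx`, `cell_lon_idx`, `year`, `start_doy`,
#'   `end_doy`, `duration`, `peak_tmax`, `cumulative_exceedance`, `mode`,
#'   `percentile`.
#' @export
extract_events <- function(temp, thresholds, percentile,
                           mode = c("day", "day_night"), min_len = 3L) {
  stopifnot(inherits(temp, "grid_daily_temperature"),
            inherits(thresholds, "threshold_field"))
  mode <- match.arg(mode)
  p_idx <- match(percentile, thresholds$percentiles)
  if (is.na(p_idx)) {
    stop("percentile ", percentile, " not in threshold field (",
         paste(thresholds$percentiles, collapse = ", "), ")", call. = FALSE)
  }
  nlat <- length(temp$grid$lat); nlon <- length(temp$grid$lon)
  doy <- temp$time$doy
  skipped <- 0L
  rows <- vector("list", nlat * nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      thx <- threshold_at(thresholds, "tmax", i, j, p_idx, doy)
      if (all(is.na(thx))) { skipped <- skipped + 1L; next }
      tx <- temp$tmax[, i, j]
      mask <- tx > thx
      if (mode == "day_night") {
        thn <- threshold_at(thresholds, "tmin", i, j, p_idx, doy)
        if (all(is.na(thn))) { skipped <- skipped + 1L; next }
        mask <- mask & (temp$tmin[, i, j] > thn)
      }
      runs <- detect_runs(mask, min_len)
      if (nrow(runs) == 0) next
      rows[[(i - 1) * nlon + j]] <- purrr::pmap_dfr(runs, function(start, length) {
        span <- start + seq_len(length) - 1L
        tibble::tibble(
          cell_lat_idx = i, cell_lon_idx = j,
          year = temp$time$year[start],
          start_doy = temp$time$doy[start],
          end_doy = temp$time$doy[start + length - 1L],
          duration = length,
          peak_tmax = max(tx[span]),
          cumulative_exceedance = sum(tx[span] - thx[span])
        )
      })
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      cell_lat_idx = integer(), cell_lon_idx = integer(), year = integer(),
      start_doy = integer(), end_doy = integer(), duration = integer(),
      peak_tmax = double(), cumulative_exceedance = double()
    )
  }
  out$mode <- mode
  out$percentile <- percentile
  attr(out, "skipped_cells") <- skipped
  class(out) <- c("heatwave_events", class(out))
  out
}

#' Classify a 3-day window on the Malaysian heatwave alert scale
#'
#' National alert levels for three consecutive days of daily Tmax:
#' level 1 ("Alert") for the 3-day minimum in `[35, 37)` degrees C,
#' level 2 ("Heatwave announcement") in `[37, 40]`, level 3 ("State of
#' emergency") above 40, and level 0 otherwise. The band edge at 37
#' degrees is assigned to level 2 and the edge at 40 to level 2, so the
#' bands partition the line.
#'
#' @param tmax_window Numeric vector of exactly 3 consecutive daily Tmax
#'   values, degrees Celsius.
#' @return Integer level 0, 1, 2 or 3. A missing value yields level 0
#'   with a warning.
#' @examples
#' classify_malaysian_level(c(36, 36, 36)) # 1
#' classify_malaysian_level(c(41, 41.5, 40.1)) # 3
#' @export
classify_malaysian_level <- function(tmax_window) {
  if (length(tmax_window) != 3) {
    stop("tmax_window must contain exactly 3 daily values", call. = FALSE)
  }
  if (anyNA(tmax_window)) {
    warning("missing value in 3-day window; returning level 0")
    return(0L)
  }
  m <- min(tmax_window)
  if (m > 40) 3L
  else if (m >= 37) 2L
  else if (m >= 35) 1L
  else 0L
}
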