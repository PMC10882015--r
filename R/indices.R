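# Annual heatwave indices: per-cell events reduced to nine area-weighted
# yearly summaries per percentile definition.
#
#   AHW   area experiencing >= 1 heatwave (km^2, day mode)
#   DHW   maximum heatwave length (days)
#   THW   peak Tmax on heatwave days (degC)
#   CTHW  cumulative exceedance over heatwave days (degC)
#   HWI   heatwave index: affected-area fraction summed over events
#   AHWN  area with joint Tmax & Tmin exceedance (% of total land area)
#   DHWN, THWN, CTHWN  night-time (day-night mode) counterparts

.index_cols <- c("AHW", "DHW", "THW", "CTHW", "HWI",
                 "AHWN", "DHWN", "THWN", "CTHWN")

#' Reduce one year's events to the nine annual heatwave indices
#'
#' Day-mode events drive `AHW` (summed area of distinct affected land
#' cells, km^2), `DHW` (maximum event duration), `THW` (maximum event
#' peak Tmax), `CTHW` (total cumulative exceedance) and `HWI` (sum over
#' events of the event cell's area divided by total land area, i.e. mean
#' affected fraction times event count). Day-night events drive the
#' night-time counterparts, with `AHWN` expressed as % of total land
#' area. A year without events yields an all-zero row flagged
#' `zero_events = TRUE`. `THW`/`THWN` have a mean-over-events variant via
#' `peak_stat = "mean"`.
#'
#' @param events A [extract_events()] table (any years/modes; filtered
#'   internally).
#' @param grid The analysis [grid_definition()].
#' @param year Calendar year to summarise.
#' @param percentile Percentile definition to summarise.
#' @param peak_stat `"max"` (default) or `"mean"` for THW/THWN.
#' @return One-row tibble with the nine indices plus `year`,
#'   `percentile`, `n_events_day`, `n_events_night`, `cells_day` (count
#'   of distinct affected cells), `zero_events`.
#' @export
annual_summary <- function(events, grid, year, percentile,
                           peak_stat = c("max", "mean")) {
  peak_stat <- match.arg(peak_stat)
  stopifnot(inherits(grid, "grid_definition"))
  areas <- grid_cell_areas(grid, land_only = TRUE)
  total_area <- sum(areas)
  ev <- dplyr::filter(tibble::as_tibble(events),
                      .data$year == !!year, .data$percentile == !!percentile)
  on_land <- grid$land_mask[cbind(ev$cell_lat_idx, ev$cell_lon_idx)]
  ev <- ev[on_land, , drop = FALSE]
  day <- dplyr::filter(ev, .data$mode == "day")
  night <- dplyr::filter(ev, .data$mode == "day_night")
  cell_area <- function(e) areas[cbind(e$cell_lat_idx, e$cell_lon_idx)]
  distinct_area <- function(e) {
    u <- dplyr::distinct(e, .data$cell_lat_idx, .data$cell_lon_idx)
    sum(areas[cbind(u$cell_lat_idx, u$cell_lon_idx)])
  }
  peak <- function(e) {
    if (nrow(e) == 0) 0 else if (peak_stat == "max") max(e$peak_tmax)
    else mean(e$peak_tmax)
  }
  tibble::tibble(
    year = as.integer(year),
    percentile = as.numeric(percentile),
    AHW = distinct_area(day),
    DHW = if (nrow(day) == 0) 0L else max(day$duration),
    THW = peak(day),
    CTHW = sum(day$cumulative_exceedance),
    HWI = sum(cell_area(day)) / total_area,
    AHWN = 100 * distinct_area(night) / total_area,
    DHWN = if (nrow(night) == 0) 0L else max(night$duration),
    THWN = peak(night),
    CTHWN = sum(night$cumulative_exceedance),
    n_events_day = nrow(day),
    n_events_night = nrow(night),
    cells_day = nrow(dplyr::distinct(day, .data$cell_lat_idx,
                                     .data$cell_lon_idx)),
    zero_events = nrow(day) == 0 && nrow(night) == 0
  )
}

#' Annual index time series over a span of years
#'
#' One [annual_summary()] row per year (zero years included), ordered,
#' ready for trend analysis and plotting.
#'
#' @param events Event table covering (at least) `years`.
#' @param grid The analysis [grid_definition()].
#' @param years Contiguous integer year range.
#' @param percentile Percentile definition.
#' @param peak_stat Passed to [annual_summary()].
#' @return Tibble of class `hw_index_series`, one row per year.
#' @export
index_timeseries <- function(events, grid, years, percentile,
                             peak_stat = c("max", "mean")) {
  peak_stat <- match.arg(peak_stat)
  if (length(years) > 1 && any(diff(years) != 1)) {
    stop("years must be a contiguous range", call. = FALSE)
  }
  out <- purrr::map_dfr(years, annual_summary, events = events, grid = grid,
                        percentile = percentile, peak_stat = peak_stat)
  class(out) <- c("hw_index_series", class(out))
  out
}

#' Plot annual heatwave index series
#'
#' One panel per index, one line per percentile definition, mirroring the
#' usual three-threshold time-series presentation.
#'
#' @param object A `hw_index_series` tibble (rows may mix percentiles).
#' @param indices Which index columns to draw (default all nine).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hw_index_series <- function(object, indices = .index_cols, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(indices),
                              names_to = "index", values_to = "value")
  long$index <- factor(long$index, levels = .index_cols)
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$value,
                                     colour = factor(.data$percentile))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL, colour = "Percentile") +
    ggplot2::theme_minimal()
}
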