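# Population exposure: overlay annual heatwave-affected cell masks with
# gridded population counts. A person counts as affected once per year
# if their cell hosts at least one event (a person-days variant weights
# by total event days instead).

#' Boolean affected-cell mask for one year
#'
#' @param events An [extract_events()] table.
#' @param grid The analysis [grid_definition()].
#' @param year Year to mask.
#' @param percentile Percentile definition.
#' @param mode `"day"` or `"day_night"`.
#' @return Logical `n_lat x n_lon` matrix: `TRUE` where the cell hosts at
#'   least one event of that year/percentile/mode.
#' @export
affected_mask <- function(events, grid, year, percentile,
                          mode = c("day", "day_night")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid_definition"))
  ev <- dplyr::filter(tibble::as_tibble(events),
                      .data$year == !!year,
                      .data$percentile == !!percentile,
                      .data$mode == !!mode)
  m <- matrix(FALSE, length(grid$lat), length(grid$lon))
  if (nrow(ev) > 0) m[cbind(ev$cell_lat_idx, ev$cell_lon_idx)] <- TRUE
  m
}

#' Population living in masked cells
#'
#' @param mask Logical matrix from [affected_mask()] (on the population
#'   grid's own geometry).
#' @param pop A [population_grid()] aggregated to the analysis grid.
#' @param year Optional expected year; a mismatch with `pop$year` is an
#'   error (guards against pairing a mask with the wrong annual raster).
#' @return Total persons in masked cells; `NA` cells contribute 0.
#' @export
affected_population <- function(mask, pop, year = NULL) {
  stopifnot(inherits(pop, "population_grid"))
  if (!is.null(year) && pop$year != year) {
    stop("population grid is for year ", pop$year, ", mask for ", year,
         call. = FALSE)
  }
  if (!identical(dim(mask), dim(pop$counts))) {
    stop("mask and population grid shapes differ", call. = FALSE)
  }
  sum(pop$counts[mask], na.rm = TRUE)
}

#' Annual affected-population time series
#'
#' For each year, sums the population of cells hosting at least one
#' heatwave event of the given percentile/mode. Population is matched by
#' exact year; with `nearest_year = TRUE` the closest available raster
#' is used instead (ties resolved to the earlier year) and recorded in
#' the output.
#'
#' @param events An [extract_events()] table.
#' @param pops List of [population_grid()]s on the analysis grid (any
#'   order; matched by their `year` field).
#' @param grid The analysis [grid_definition()].
#' @param years Integer years to evaluate.
#' @param percentile Percentile definition.
#' @param mode `"day"` (default) or `"day_night"`.
#' @param nearest_year Fall back to the nearest population year.
#' @param person_days Weight each cell by its total event days that year
#'   instead of counting persons once.
#' @return Tibble of class `hw_exposure_series`: `year`, `percentile`,
#'   `mode`, `affected_population`, `total_population`, `pop_year_used`.
#' @export
exposure_series <- function(events, pops, grid, years, percentile,
                            mode = c("day", "day_night"),
                            nearest_year = FALSE, person_days = FALSE) {
  mode <- match.arg(mode)
  if (length(pops) == 0) stop("no population data supplied", call. = FALSE)
  stopifnot(all(purrr::map_lgl(pops, inherits, "population_grid")))
  pop_years <- purrr::map_int(pops, "year")
  ev <- tibble::as_tibble(events)
  out <- purrr::map_dfr(years, function(yr) {
    k <- match(yr, pop_years)
    if (is.na(k)) {
      if (!nearest_year) {
        stop("no population grid for year ", yr,
             " (set nearest_year = TRUE to use the closest raster)",
             call. = FALSE)
      }
      k <- which.min(abs(pop_years - yr))
    }
    pop <- pops[[k]]
    if (person_days) {
      evy <- dplyr::filter(ev, .data$year == yr,
                           .data$percentile == !!percentile,
                           .data$mode == !!mode)
      days <- matrix(0, length(grid$lat), length(grid$lon))
      for (r in seq_len(nrow(evy))) {
        days[evy$cell_lat_idx[r], evy$cell_lon_idx[r]] <-
          days[evy$cell_lat_idx[r], evy$cell_lon_idx[r]] + evy$duration[r]
      }
      cnt <- pop$counts
      cnt[is.na(cnt)] <- 0
      aff <- sum(cnt * days)
    } else {
      m <- affected_mask(ev, grid, yr, percentile, mode)
      aff <- affected_population(m, pop)
    }
    tibble::tibble(
      year = as.integer(yr), percentile = as.numeric(percentile),
      mode = mode, affected_population = aff,
      total_population = sum(pop$counts, na.rm = TRUE),
      pop_year_used = pop$year
    )
  })
  class(out) <- c("hw_exposure_series", class(out))
  out
}

#' Plot affected-population time series
#'
#' One line per percentile definition, the conventional three-threshold
#' presentation of annual heat exposure.
#'
#' @param object A `hw_exposure_series` tibble (rows may stack several
#'   percentiles).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hw_exposure_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$year, .data$affected_population,
                               colour = factor(.data$percentile))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Affected population (persons)",
                  colour = "Percentile") +
    ggplot2::theme_minimal()
}
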