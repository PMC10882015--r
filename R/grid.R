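#' Define a regular latitude-longitude analysis grid
#'
#' A grid is described by ascending cell-center coordinates, a common cell
#' size, and a land mask. All package containers (temperature cubes,
#' threshold fields, population grids) carry one of these.
#'
#' @param lat_centers Numeric vector of cell-center latitudes, degrees,
#'   strictly ascending and regularly spaced (tolerance 1e-6 degrees).
#' @param lon_centers Numeric vector of cell-center longitudes, degrees,
#'   strictly ascending and regularly spaced.
#' @param cell_size Cell edge length in degrees. Defaults to the latitude
#'   spacing (or the longitude spacing for a single-row grid).
#' @param land_mask Logical matrix `length(lat_centers)` x
#'   `length(lon_centers)`; `TRUE` marks land cells that take part in area
#'   and index computations. Defaults to all-land.
#'
#' @return An object of class `grid_definition`: a list with elements
#'   `lat`, `lon`, `cell_size`, `land_mask`.
#' @examples
#' g <- grid_definition(seq(1.125, 6.375, by = 0.25), seq(99.375, 104.125, by = 0.25))
#' dim(g$land_mask)
#' @export
grid_definition <- function(lat_centers, lon_centers, cell_size = NULL,
                            land_mask = NULL) {
  lat_centers <- as.numeric(lat_centers)
  lon_centers <- as.numeric(lon_centers)
  check_regular_axis(lat_centers, "lat_centers")
  check_regular_axis(lon_centers, "lon_centers")
  if (is.null(cell_size)) {
    cell_size <- if (length(lat_centers) > 1) {
      diff(lat_centers)[1]
    } else if (length(lon_centers) > 1) {
      diff(lon_centers)[1]
    } else {
      stop("cell_size must be given for a 1x1 grid", call. = FALSE)
    }
  }
  nlat <- length(lat_centers)
  nlon <- length(lon_centers)
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, nlat, nlon)
  }
  if (!identical(dim(land_mask), c(nlat, nlon)) &&
      length(land_mask) != nlat * nlon) {
    stop("land_mask must be ", nlat, " x ", nlon, call. = FALSE)
  }
  land_mask <- matrix(as.logical(land_mask), nlat, nlon)
  structure(
    list(lat = lat_centers, lon = lon_centers,
         cell_size = as.numeric(cell_size), land_mask = land_mask),
    class = "grid_definition"
  )
}

check_regular_axis <- function(x, name, tol = 1e-6) {
  if (length(x) < 1) stop(name, " is empty", call. = FALSE)
  if (length(x) > 1) {
    d <- diff(x)
    if (any(d <= 0)) stop(name, " must be strictly ascending", call. = FALSE)
    if (max(d) - min(d) > tol) {
      stop(name, " must be regularly spaced (tolerance 1e-6 degrees)",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.grid_definition <- function(x, ...) {
  cat("<grid_definition> ", length(x$lat), " x ", length(x$lon),
      " cells of ", x$cell_size, " deg; ",
      sum(x$land_mask), " land cells\n", sep = "")
  invisible(x)
}

#' Spherical-Earth area of a grid cell, in square kilometres
#'
#' Area of the latitude band slice `R^2 * dlon * (sin(top) - sin(bottom))`
#' on a sphere of radius 6371 km, where the cell extends `cell_size / 2`
#' either side of its center latitude.
#'
#' @param lat_center Cell-center latitude(s) in degrees, `abs(lat) <= 90`.
#'   Vectorised.
#' @param cell_size Cell edge in degrees (same in lat and lon).
#' @return Area(s) in km^2.
#' @examples
#' cell_area_km2(0, 0.25) # ~772.6 km^2 on the equator
#' @export
cell_area_km2 <- function(lat_center, cell_size) {
  if (any(abs(lat_center) > 90)) {
    stop("abs(lat_center) must be <= 90", call. = FALSE)
  }
  R <- 6371
  half <- cell_size / 2
  top <- pmin(lat_center + half, 90) * pi / 180
  bot <- pmax(lat_center - half, -90) * pi / 180
  R^2 * (cell_size * pi / 180) * (sin(top) - sin(bot))
}

#' Per-cell areas of a grid as a matrix
#'
#' @param grid A [grid_definition()].
#' @param land_only If `TRUE`, ocean (non-land) cells get area 0.
#' @return Matrix `n_lat x n_lon` of areas in km^2.
#' @export
grid_cell_areas <- function(grid, land_only = FALSE) {
  a <- matrix(cell_area_km2(grid$lat, grid$cell_size),
              nrow = length(grid$lat), ncol = length(grid$lon))
  if (land_only) a[!grid$land_mask] <- 0
  a
}

#' Total land area of a grid in km^2
#' @param grid A [grid_definition()].
#' @return Scalar km^2.
#' @export
total_land_area_km2 <- function(grid) {
  sum(grid_cell_areas(grid, land_only = TRUE))
}
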