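#' Construct a gridded daily temperature cube
#'
#' Holds daily Tmax/Tmin on a regular lat-lon grid with a gap-free daily
#' time axis. Missing values are `NA` slots, never absent rows. The time
#' axis is a (year, day-of-year) table so that a 365-day no-leap calendar
#' (used by the synthetic generator) and the true Gregorian calendar (used
#' for real data) share one representation.
#'
#' @param grid A [grid_definition()].
#' @param time Tibble/data frame with integer columns `year` and `doy`
#'   (day of year), in strictly increasing chronological order with no gaps
#'   at the daily step.
#' @param tmax,tmin Numeric arrays `n_time x n_lat x n_lon`, degrees
#'   Celsius. `tmax >= tmin` is enforced wherever both are present.
#' @param calendar `"noleap"` (365-day years) or `"gregorian"`.
#'
#' @return Object of class `grid_daily_temperature`.
#' @export
grid_daily_temperature <- function(grid, time, tmax, tmin,
                                   calendar = c("noleap", "gregorian")) {
  calendar <- match.arg(calendar)
  stopifnot(inherits(grid, "grid_definition"))
  time <- tibble::as_tibble(time)
  if (!all(c("year", "doy") %in% names(time))) {
    stop("time must have columns year and doy", call. = FALSE)
  }
  nt <- nrow(time)
  dims <- c(nt, length(grid$lat), length(grid$lon))
  tmax <- array(as.numeric(tmax), dims)
  tmin <- array(as.numeric(tmin), dims)
  bad <- which(!is.na(tmax) & !is.na(tmin) & tmax < tmin)
  if (length(bad) > 0) {
    stop("tmax < tmin at ", length(bad), " cell-days", call. = FALSE)
  }
  # gap-free daily axis
  ylen <- function(y) if (calendar == "noleap") 365L else 365L + leap_year(y)
  if (nt > 1) {
    yy <- time$year; dd <- time$doy
    step_ok <- (yy[-1] == yy[-nt] & dd[-1] == dd[-nt] + 1L) |
      (yy[-1] == yy[-nt] + 1L & dd[-1] == 1L & dd[-nt] == ylen(yy[-nt]))
    if (!all(step_ok)) {
      stop("time axis is not gap-free at the daily step", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, time = time, tmax = tmax, tmin = tmin,
         calendar = calendar),
    class = "grid_daily_temperature"
  )
}

leap_year <- function(y) {
  as.integer((y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0)
}

#' @export
print.grid_daily_temperature <- function(x, ...) {
  cat("<grid_daily_temperature> ", nrow(x$time), " days (",
      min(x$time$year), "-", max(x$time$year), ", ", x$calendar,
      " calendar) on a ", length(x$grid$lat), "x", length(x$grid$lon),
      " grid\n", sep = "")
  invisible(x)
}

#' No-leap daily time table for a span of years
#' @param start_year,n_years Integers.
#' @return Tibble with `year`, `doy` (1..365) per day.
#' @keywords internal
noleap_time_table <- function(start_year, n_years) {
  tibble::tibble(
    year = rep(seq.int(start_year, length.out = n_years), each = 365L),
    doy = rep(1:365, times = n_years)
  )
}
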