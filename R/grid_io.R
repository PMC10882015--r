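# File exchange: the package's plain-text cube format for daily
# temperature, ESRI ASCII grids for population rasters, and lossless CSV
# export of tabular results.

#' Write a daily temperature cube to the package's CSV cube format
#'
#' Long-format CSV (`year, doy, lat, lon, tmax, tmin`) preceded by
#' `#key: value` metadata lines (`units`, `calendar`, `cell_size`,
#' `lat_order`). The format is self-describing so a reader can restore
#' the cube, convert Kelvin, and normalise latitude order.
#'
#' @param temp A [grid_daily_temperature()].
#' @param path Output file path.
#' @param units `"degC"` or `"K"` (values converted on write).
#' @param lat_order `"asc"` or `"desc"` row ordering on disk (reanalysis
#'   products commonly ship descending latitude).
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(temp, path, units = c("degC", "K"),
                                  lat_order = c("asc", "desc")) {
  units <- match.arg(units)
  lat_order <- match.arg(lat_order)
  g <- temp$grid
  lat_idx <- seq_along(g$lat)
  if (lat_order == "desc") lat_idx <- rev(lat_idx)
  off <- if (units == "K") 273.15 else 0
  df <- expand.grid(ti = seq_len(nrow(temp$time)),
                    la = lat_idx, lo = seq_along(g$lon))
  out <- data.frame(
    year = temp$time$year[df$ti],
    doy = temp$time$doy[df$ti],
    lat = g$lat[df$la],
    lon = g$lon[df$lo],
    tmax = temp$tmax[cbind(df$ti, df$la, df$lo)] + off,
    tmin = temp$tmin[cbind(df$ti, df$la, df$lo)] + off
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#units: ", units),
    paste0("#calendar: ", temp$calendar),
    paste0("#cell_size: ", format(g$cell_size, digits = 17)),
    paste0("#lat_order: ", lat_order)
  ), con)
  utils::write.table(format_num_df(out), con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a daily temperature cube from the CSV cube format
#'
#' Latitudes are normalised to ascending regardless of on-disk order, and
#' values declared Kelvin (metadata or `unit_hint`) are converted to
#' degrees Celsius.
#'
#' @param path File written by [write_temperature_csv()] (or compatible).
#' @param unit_hint Optional `"degC"`/`"K"` override when the file lacks a
#'   `#units` line. A conflict with declared metadata is an error.
#' @param land_mask Optional logical matrix for the restored grid.
#' @return A [grid_daily_temperature()].
#' @export
read_temperature_csv <- function(path, unit_hint = NULL, land_mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- readLines(path, n = 50)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- parse_meta(meta_lines)
  units <- meta[["units"]]
  if (!is.null(unit_hint)) {
    if (!is.null(units) && units != unit_hint) {
      stop("unit_hint ", unit_hint, " conflicts with declared units ",
           units, call. = FALSE)
    }
    units <- unit_hint
  }
  if (is.null(units)) units <- "degC"
  if (!units %in% c("degC", "K")) {
    stop("unsupported units: ", units, call. = FALSE)
  }
  calendar <- meta[["calendar"]] %||% "gregorian"
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("year", "doy", "lat", "lon", "tmax", "tmin")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("temperature cube file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  time <- unique(df[order(df$year, df$doy), c("year", "doy")])
  nt <- nrow(time)
  key_t <- match(paste(df$year, df$doy), paste(time$year, time$doy))
  key_la <- match(df$lat, lat)
  key_lo <- match(df$lon, lon)
  off <- if (units == "K") -273.15 else 0
  tmax <- array(NA_real_, c(nt, length(lat), length(lon)))
  tmin <- tmax
  tmax[cbind(key_t, key_la, key_lo)] <- df$tmax + off
  tmin[cbind(key_t, key_la, key_lo)] <- df$tmin + off
  cs <- if (!is.null(meta[["cell_size"]])) as.numeric(meta[["cell_size"]]) else NULL
  g <- grid_definition(lat, lon, cell_size = cs, land_mask = land_mask)
  grid_daily_temperature(g, time, tmax, tmin, calendar = calendar)
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Construct an annual population grid
#'
#' @param grid A [grid_definition()].
#' @param counts Numeric matrix `n_lat x n_lon` of person counts, `NA`
#'   allowed, negatives rejected.
#' @param year Calendar year the counts refer to.
#' @return Object of class `population_grid`.
#' @export
population_grid <- function(grid, counts, year) {
  stopifnot(inherits(grid, "grid_definition"))
  counts <- matrix(as.numeric(counts), length(grid$lat), length(grid$lon))
  if (any(counts < 0, na.rm = TRUE)) {
    stop("population counts must be non-negative", call. = FALSE)
  }
  structure(list(grid = grid, counts = counts, year = as.integer(year)),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat("<population_grid> year ", x$year, ", ",
      length(x$grid$lat), "x", length(x$grid$lon), " cells, total ",
      format(sum(x$counts, na.rm = TRUE), big.mark = ","), " persons (",
      sum(is.na(x$counts)), " NA cells)\n", sep = "")
  invisible(x)
}

#' Write a population grid as an ESRI ASCII raster
#'
#' @param pop A [population_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(pop, path, nodata = -9999) {
  g <- pop$grid
  nr <- length(g$lat); nc <- length(g$lon)
  vals <- pop$counts
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.17g", min(g$lon) - g$cell_size / 2)),
    paste("yllcorner", sprintf("%.17g", min(g$lat) - g$cell_size / 2)),
    paste("cellsize", sprintf("%.17g", g$cell_size)),
    paste("NODATA_value", sprintf("%.17g", nodata))
  ), con)
  # ESRI ASCII rows run north -> south
  for (i in rev(seq_len(nr))) {
    writeLines(paste(sprintf("%.17g", vals[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a population raster from an ESRI ASCII grid
#'
#' The georeference (origin, cell size) is taken from the header; the
#' nodata sentinel maps to `NA`. Rows on disk run north to south and are
#' flipped to the package's ascending-latitude convention.
#'
#' @param path `.asc` file.
#' @param year Calendar year to stamp on the result.
#' @return A [population_grid()].
#' @export
read_population_raster <- function(path, year) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) ||
      !(("xllcorner" %in% names(hdr) && "yllcorner" %in% names(hdr)) ||
        ("xllcenter" %in% names(hdr) && "yllcenter" %in% names(hdr)))) {
    stop("not a georeferenced ESRI ASCII grid: missing header fields",
         call. = FALSE)
  }
  nc <- hdr$ncols; nr <- hdr$nrows; cs <- hdr$cellsize
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner + cs / 2 else hdr$xllcenter
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner + cs / 2 else hdr$yllcenter
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " raster values, found ", length(vals),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # north->south on disk
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  g <- grid_definition(y0 + (seq_len(nr) - 1) * cs,
                       x0 + (seq_len(nc) - 1) * cs, cell_size = cs)
  population_grid(g, m, year)
}

#' Aggregate a fine population raster to an analysis grid
#'
#' Each target cell receives `sum(count * fractional area overlap)` over
#' fine cells, skipping `NA` fine cells. When the fine grid nests exactly
#' in the target (integer subdivision) this reduces to a block sum, and
#' the global total is conserved exactly in the absence of `NA`.
#'
#' @param fine A [population_grid()] at finer (or equal) resolution.
#' @param target A [grid_definition()] whose extent overlaps `fine`.
#' @return A [population_grid()] on `target`.
#' @export
aggregate_population_to_grid <- function(fine, target) {
  stopifnot(inherits(fine, "population_grid"),
            inherits(target, "grid_definition"))
  wlat <- axis_overlap_weights(fine$grid$lat, fine$grid$cell_size,
                               target$lat, target$cell_size)
  wlon <- axis_overlap_weights(fine$grid$lon, fine$grid$cell_size,
                               target$lon, target$cell_size)
  if (all(wlat == 0) || all(wlon == 0)) {
    stop("fine and target grids have disjoint extents", call. = FALSE)
  }
  counts <- fine$counts
  counts[is.na(counts)] <- 0  # "did not include NA" aggregation rule
  coarse <- t(wlat) %*% counts %*% wlon
  population_grid(target, coarse, fine$year)
}

# Fractional overlap of each fine interval with each target interval,
# as a fraction of the *fine* cell extent (so weights on one axis sum to
# <= 1 per fine cell; products across axes give area fractions).
axis_overlap_weights <- function(fine_centers, fine_size,
                                 target_centers, target_size) {
  flo <- fine_centers - fine_size / 2
  fhi <- fine_centers + fine_size / 2
  tlo <- target_centers - target_size / 2
  thi <- target_centers + target_size / 2
  ov <- outer(fhi, thi, pmin) - outer(flo, tlo, pmax)
  ov[ov < 0] <- 0
  ov / fine_size
}

#' Export a tabular result as lossless CSV
#'
#' Doubles are written with 17 significant digits and a C-locale decimal
#' point, so `read.csv()` restores them bit-exactly.
#'
#' @param x Data frame (annual index series, trend table, exposure series).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  utils::write.table(format_num_df(as.data.frame(x)), path, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
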