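# End-to-end orchestration: simulate study inputs to disk, run the
# detection -> indices -> trends -> exposure chain, and render a report.
# A thin command-line wrapper over these functions ships in
# inst/cli/heatwaves.R (subcommands simulate | run | report).

#' Simulate study inputs and write them as fixture files
#'
#' Writes a synthetic daily temperature cube (CSV cube format), one
#' population raster per requested year (ESRI ASCII), the ground-truth
#' ledger of any injected events (CSV), and a manifest with MD5
#' checksums. Outputs are bit-identical across runs with the same
#' configurations and seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @param climate_cfg A [synthetic_climate_config()].
#' @param pop_cfg A [synthetic_population_config()] or `NULL` to skip
#'   population.
#' @param pop_years Years to stamp population rasters with (one file per
#'   year; counts drawn once per year with `pop_cfg$seed + offset`).
#' @param events Optional [injected_events()] to add to the cube.
#' @return Invisibly, a tibble manifest (`file`, `md5`).
#' @export
simulate_heatwave_inputs <- function(out_dir,
                                     climate_cfg = synthetic_climate_config(),
                                     pop_cfg = synthetic_population_config(),
                                     pop_years = NULL,
                                     events = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  temp <- generate_daily_temperature(climate_cfg)
  if (!is.null(events)) {
    temp <- inject_heatwaves(temp, events)
    export_csv(attr(temp, "ground_truth"),
               file.path(out_dir, "ground_truth_events.csv"))
  }
  write_temperature_csv(temp, file.path(out_dir, "temperature.csv"))
  if (!is.null(pop_cfg)) {
    if (is.null(pop_years)) {
      pop_years <- max(temp$time$year)
    }
    for (k in seq_along(pop_years)) {
      cfg_y <- pop_cfg
      cfg_y$seed <- pop_cfg$seed + k - 1L
      pop <- generate_population(cfg_y, temp$grid, year = pop_years[k])
      write_esri_ascii(pop, file.path(out_dir,
                                      sprintf("population_%d.asc",
                                              pop_years[k])))
    }
  }
  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- tibble::tibble(file = basename(files),
                             md5 = tools::md5sum(files))
  export_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Run the full heatwave analysis
#'
#' Thresholds -> events (per percentile and mode) -> annual indices ->
#' decadal trend table -> (optionally) population exposure. All results
#' are returned as tibbles; when `out_dir` is given they are also written
#' as CSV, together with a log of the definition switches in effect.
#'
#' @param temp A [grid_daily_temperature()] or a path readable by
#'   [read_temperature_csv()].
#' @param pops Optional list of [population_grid()]s (fine resolution is
#'   fine; each is aggregated to the analysis grid), or paths to ESRI
#'   ASCII rasters named `population_<year>.asc`.
#' @param ref_period Reference window for thresholds, default
#'   `c(1961, 1990)`.
#' @param percentiles Threshold percentiles, default `c(95, 97.5, 99)`.
#' @param min_run_days Minimum event length, default 3.
#' @param years Years to summarise (default: all years in the cube).
#' @param exposure_years Years for the exposure series (default: the
#'   population years available).
#' @param nearest_year Passed to [exposure_series()].
#' @param out_dir Optional output directory for CSVs.
#' @param ... Passed to [compute_thresholds()] (`pool`,
#'   `max_missing_fraction`) .
#' @return Object of class `heatwave_analysis`: list with `events`,
#'   `indices` (`hw_index_series`, stacked percentiles), `trends`,
#'   `exposure` (or `NULL`), `thresholds`, `grid`, `settings`.
#' @export
run_heatwave_pipeline <- function(temp, pops = NULL,
                                  ref_period = c(1961, 1990),
                                  percentiles = c(95, 97.5, 99),
                                  min_run_days = 3L,
                                  years = NULL, exposure_years = NULL,
                                  nearest_year = FALSE,
                                  out_dir = NULL, ...) {
  if (is.character(temp)) temp <- read_temperature_csv(temp)
  stopifnot(inherits(temp, "grid_daily_temperature"))
  if (is.null(years)) years <- sort(unique(temp$time$year))
  if (is.character(pops)) {
    yrs <- as.integer(sub(".*population_(\\d+)\\.asc$", "\\1", pops))
    pops <- purrr::map2(pops, yrs, read_population_raster)
  }
  if (!is.null(pops)) {
    pops <- purrr::map(pops, function(p) {
      if (identical(dim(p$counts),
                    c(length(temp$grid$lat), length(temp$grid$lon)))) p
      else aggregate_population_to_grid(p, temp$grid)
    })
  }
  thr <- compute_thresholds(temp, ref_period, percentiles, ...)
  combos <- expand.grid(percentile = percentiles,
                        mode = c("day", "day_night"),
                        stringsAsFactors = FALSE)
  events <- purrr::pmap_dfr(combos, function(percentile, mode) {
    extract_events(temp, thr, percentile, mode, min_len = min_run_days)
  })
  indices <- purrr::map_dfr(percentiles, function(p) {
    index_timeseries(events, temp$grid, years, p)
  })
  class(indices) <- c("hw_index_series", class(indices))
  trends <- trend_table(indices)
  exposure <- NULL
  if (!is.null(pops)) {
    if (is.null(exposure_years)) {
      exposure_years <- intersect(years,
                                  sort(purrr::map_int(pops, "year")))
    }
    if (length(exposure_years) > 0) {
      exposure <- purrr::map_dfr(percentiles, function(p) {
        exposure_series(events, pops, temp$grid, exposure_years, p,
                        nearest_year = nearest_year)
      })
      class(exposure) <- c("hw_exposure_series", class(exposure))
    }
  }
  settings <- tibble::tibble(
    key = c("ref_period", "percentiles", "min_run_days", "modes",
            "threshold_pool", "quantile_type", "inequality",
            "year_attribution"),
    value = c(paste(ref_period, collapse = "-"),
              paste(percentiles, collapse = ","),
              as.character(min_run_days), "day,day_night", thr$pool,
              "7 (linear interpolation of order statistics)",
              "strict (Tmax > threshold)", "event start date")
  )
  res <- structure(
    list(events = events, indices = indices, trends = trends,
         exposure = exposure, thresholds = thr, grid = temp$grid,
         settings = settings),
    class = "heatwave_analysis"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    export_csv(events, file.path(out_dir, "events.csv"))
    export_csv(indices, file.path(out_dir, "annual_indices.csv"))
    export_csv(trends, file.path(out_dir, "trend_table.csv"))
    if (!is.null(exposure)) {
      export_csv(exposure, file.path(out_dir, "exposure.csv"))
    }
    export_csv(settings, file.path(out_dir, "settings.csv"))
  }
  res
}

#' @export
print.heatwave_analysis <- function(x, ...) {
  cat("<heatwave_analysis>\n",
      "  events:   ", nrow(x$events), " (",
      sum(x$events$mode == "day"), " day / ",
      sum(x$events$mode == "day_night"), " day-night)\n",
      "  years:    ", min(x$indices$year), "-", max(x$indices$year), "\n",
      "  trends:   ", nrow(x$trends), " index x percentile cells, ",
      sum(x$trends$significant), " significant at alpha = 0.05\n", sep = "")
  invisible(x)
}

#' Render plots for a pipeline result
#'
#' Writes the nine-index time-series panel and, when exposure was
#' computed, the affected-population series, as PNG files.
#'
#' @param result A [run_heatwave_pipeline()] result.
#' @param out_dir Output directory.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Character vector of files written, invisibly.
#' @export
report_heatwave_pipeline <- function(result, out_dir,
                                     width = 10, height = 7, dpi = 150) {
  stopifnot(inherits(result, "heatwave_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(out_dir, "annual_indices.png")
  ggplot2::ggsave(f, autoplot(result$indices), width = width,
                  height = height, dpi = dpi)
  files <- c(files, f)
  if (!is.null(result$exposure)) {
    f <- file.path(out_dir, "exposure.png")
    ggplot2::ggsave(f, autoplot(result$exposure), width = width,
                    height = height * 0.6, dpi = dpi)
    files <- c(files, f)
  }
  invisible(files)
}
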