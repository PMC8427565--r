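#' Configuration for the synthetic hourly weather field
#'
#' Hourly temperature and wind on a coarse grid covering the landscape
#' (emulating reanalysis weather at a much coarser resolution than the 250 m
#' forage grids). Temperature combines a seasonal cycle, a diurnal cycle
#' peaking mid-afternoon, a cool-coast offset and AR(1) noise; wind is a
#' truncated-Gaussian AR(1) series around a configurable mean. Defaults span
#' roughly 0-25 degrees C across the season.
#'
#' @param landscape A [landscape_config()] giving the spatial extent and the
#'   coast edge.
#' @param ncx,ncy Coarse-grid cell counts.
#' @param temp_mean Seasonal baseline, degrees C.
#' @param temp_seasonal_amp Amplitude of the half-sine seasonal cycle.
#' @param temp_diurnal_amp Amplitude of the diurnal cycle.
#' @param temp_sd Innovation scale of the AR(1) temperature noise.
#' @param coast_cool Temperature depression at the coast, degrees C.
#' @param wind_mean,wind_sd Wind mean and AR(1) innovation scale, m/s.
#' @param heatwave Optional `list(week =, delta =)` adding `delta` degrees
#'   during one week.
#' @param n_days Season length in days.
#' @return A `weather_config` list.
#' @export
weather_config <- function(landscape, ncx = 3, ncy = 2,
                           temp_mean = 8, temp_seasonal_amp = 7,
                           temp_diurnal_amp = 6, temp_sd = 2.5,
                           coast_cool = 2,
                           wind_mean = 4, wind_sd = 2.2,
                           heatwave = NULL, n_days = 92) {
  stopifnot(inherits(landscape, "landscape_config"))
  structure(
    list(
      ncx = as.integer(ncx), ncy = as.integer(ncy),
      extent_x = landscape$grid_nx * landscape$cell_size,
      extent_y = landscape$grid_ny * landscape$cell_size,
      coast_edge = landscape$coast_edge,
      temp_mean = temp_mean, temp_seasonal_amp = temp_seasonal_amp,
      temp_diurnal_amp = temp_diurnal_amp, temp_sd = temp_sd,
      coast_cool = coast_cool,
      wind_mean = wind_mean, wind_sd = wind_sd,
      heatwave = heatwave, n_days = as.integer(n_days)
    ),
    class = "weather_config"
  )
}

#' Generate a synthetic hourly weather field
#'
#' @param config A [weather_config()].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   fields.
#' @param year Calendar year of the season start (1 June, UTC).
#' @return A `weather_field`: matrices `temperature` and `wind`
#'   (coarse-cell x hour), the coarse-grid geometry and the hourly time axis.
#' @export
generate_weather <- function(config, seed = 1L, year = 2017L) {
  stopifnot(inherits(config, "weather_config"))
  set.seed(seed)
  nh <- config$n_days * 24L
  ncell <- config$ncx * config$ncy
  hour <- seq_len(nh) - 1L
  day <- hour %/% 24L + 1L
  hod <- hour %% 24L

  seas <- config$temp_mean + config$temp_seasonal_amp * sin(pi * day / config$n_days)
  diur <- config$temp_diurnal_amp * cos(2 * pi * (hod - 14) / 24)
  ccx <- (rep(seq_len(config$ncx), config$ncy) - 0.5) / config$ncx
  ccy <- (rep(seq_len(config$ncy), each = config$ncx) - 0.5) / config$ncy
  coastness <- switch(config$coast_edge, N = ccy, S = 1 - ccy, E = ccx, W = 1 - ccx)

  ar1 <- function(n, sd, phi = 0.8) {
    if (sd <= 0) return(numeric(n))
    e <- stats::rnorm(n, 0, sd)
    stats::filter(e, phi, method = "recursive") * sqrt(1 - phi^2)
  }
  temperature <- matrix(0, ncell, nh)
  wind <- matrix(0, ncell, nh)
  for (c in seq_len(ncell)) {
    temperature[c, ] <- seas + diur - config$coast_cool * coastness[c] +
      as.numeric(ar1(nh, config$temp_sd))
    wind[c, ] <- pmax(0, config$wind_mean + as.numeric(ar1(nh, config$wind_sd)))
  }
  if (!is.null(config$heatwave)) {
    hw <- config$heatwave
    in_week <- day > (hw$week - 1) * 7 & day <= hw$week * 7
    temperature[, in_week] <- temperature[, in_week] + hw$delta
  }
  t0 <- as.POSIXct(sprintf("%04d-06-01 00:00:00", year), tz = "UTC")
  structure(
    list(
      temperature = temperature, wind = wind,
      ncx = config$ncx, ncy = config$ncy,
      x_breaks = seq(0, config$extent_x, length.out = config$ncx + 1),
      y_breaks = seq(0, config$extent_y, length.out = config$ncy + 1),
      t0 = t0, n_hours = nh, year = as.integer(year), config = config
    ),
    class = "weather_field"
  )
}

#' @export
print.weather_field <- function(x, ...) {
  cat(sprintf(
    "<weather_field> %d x %d coarse cells, %d hours from %s; temp %.1f..%.1f C, wind %.1f..%.1f m/s\n",
    x$ncx, x$ncy, x$n_hours, format(x$t0, "%Y-%m-%d"),
    min(x$temperature), max(x$temperature), min(x$wind), max(x$wind)
  ))
  invisible(x)
}
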