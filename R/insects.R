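#' Mosquito activity index
#'
#' Temperature/wind index of mosquito harassment in \[0, 1\]; higher values
#' indicate greater insect activity. The index is 1 at temperatures of 18
#' degrees C or more with no wind, 0 below 6 degrees C or above 6 m/s wind.
#' Between those endpoints the index is the product of two linear ramps,
#' `f_T` rising from 0 at 6 C to 1 at 18 C and `f_W` falling from 1 at
#' 0 m/s to 0 at 6 m/s (both clamped). The separable ramp product is this
#' package's interpolation between the published endpoint conditions; it is
#' continuous, monotone in each argument, and isolated here so an alternative
#' interpolation can be swapped in.
#'
#' @param temperature Air temperature, degrees C.
#' @param wind Wind speed, m/s (must be non-negative).
#' @return Numeric vector in \[0, 1\].
#' @examples
#' mosquito_index(18, 0)  # 1
#' mosquito_index(12, 3)  # 0.25
#' @export
mosquito_index <- function(temperature, wind) {
  insect_ramp(temperature, wind, t0 = 6, t1 = 18, w1 = 6)
}

#' Oestrid fly activity index
#'
#' Temperature/wind index of warble/botfly harassment in \[0, 1\]. The index
#' is 1 at 18 degrees C or more with no wind, 0 below 13 degrees C or above
#' 9 m/s wind; in between it is the product of linear ramps (0 at 13 C to
#' 1 at 18 C; 1 at 0 m/s to 0 at 9 m/s), clamped.
#'
#' @inheritParams mosquito_index
#' @return Numeric vector in \[0, 1\].
#' @examples
#' oestrid_index(20, 0)     # 1
#' oestrid_index(15.5, 4.5) # 0.25
#' @export
oestrid_index <- function(temperature, wind) {
  insect_ramp(temperature, wind, t0 = 13, t1 = 18, w1 = 9)
}

# Shared clamped-ramp product. At exactly t0 or exactly w1 the ramp value (0)
# applies, consistent with continuity and with the strict published
# inequalities.
insect_ramp <- function(temperature, wind, t0, t1, w1) {
  if (any(is.na(wind)) || any(is.na(temperature))) {
    stopf("insect indices require non-missing temperature and wind")
  }
  if (any(wind < 0)) stopf("wind speed must be non-negative")
  ft <- pmin(pmax((temperature - t0) / (t1 - t0), 0), 1)
  fw <- pmin(pmax(1 - wind / w1, 0), 1)
  ft * fw
}

#' Attribute insect indices to points by space-time lookup
#'
#' Each point receives the mosquito (`mi`) and oestrid (`oi`) index computed
#' from the weather field's containing coarse cell at the containing hour.
#' With `periods_only = TRUE` (the default, mirroring how the indices feed the
#' selection analyses) `mi` is kept only for points in the mosquito period and
#' `oi` only for points in the oestrid period; other rows carry `NA`, since
#' each index enters the analysis only during its own insect season. Points
#' must already carry a `period` column in that case (see
#' [assign_periods()]).
#'
#' @param points Data frame with `x`, `y`, `timestamp` (and `period` when
#'   `periods_only = TRUE`).
#' @param weather A [generate_weather()] field covering all points.
#' @param periods_only Restrict each index to its insect period?
#' @return `points` with `mi` and `oi` columns appended.
#' @export
attribute_insects <- function(points, weather, periods_only = TRUE) {
  stopifnot(inherits(weather, "weather_field"))
  cx <- findInterval(points$x, weather$x_breaks, rightmost.closed = TRUE)
  cy <- findInterval(points$y, weather$y_breaks, rightmost.closed = TRUE)
  hr <- floor(as.numeric(difftime(points$timestamp, weather$t0, units = "hours"))) + 1
  bad <- cx < 1 | cx > weather$ncx | cy < 1 | cy > weather$ncy |
    hr < 1 | hr > weather$n_hours | is.na(hr)
  if (any(bad)) {
    stopf(
      "%d point(s) fall outside the weather field's space-time extent (rows: %s)",
      sum(bad), paste(utils::head(which(bad), 10L), collapse = ", ")
    )
  }
  cell <- cx + (cy - 1L) * weather$ncx
  idx <- cbind(cell, hr)
  tt <- weather$temperature[idx]
  ww <- weather$wind[idx]
  out <- points
  out$mi <- mosquito_index(tt, ww)
  out$oi <- oestrid_index(tt, ww)
  if (periods_only) {
    if (!"period" %in% names(out)) {
      stopf("periods_only = TRUE requires a 'period' column (run assign_periods first)")
    }
    out$mi[out$period != "mosquito"] <- NA_real_
    out$oi[out$period != "oestrid"] <- NA_real_
  }
  out
}
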