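#' Summer period calendar
#'
#' Builds the calendar of behavioural periods used throughout the analysis,
#' expressed in ordinal study days (day 1 = 1 June). The five periods are
#' calving (1-15 Jun), post-calving (16-24 Jun), mosquito harassment
#' (25 Jun - 15 Jul), oestrid fly harassment (29 Jul - 7 Aug) and end of
#' summer (16-31 Aug). The gaps 16-28 Jul and 8-15 Aug belong to no period:
#' caribou are typically relocating between habitat areas then and those days
#' are excluded from selection analyses. Calving is retained as a label but
#' flagged as excluded from selection analyses (persistent snow masks most
#' forage predictions in early June).
#'
#' @return A data frame with one row per period: `period`, `start_day`,
#'   `end_day` (inclusive ordinal study days), `season` ("early"/"late") and
#'   `analysis` (FALSE for calving).
#' @export
period_calendar <- function() {
  data.frame(
    period    = c("calving", "post_calving", "mosquito", "oestrid", "end_of_summer"),
    start_day = c(1L, 16L, 25L, 59L, 77L),
    end_day   = c(15L, 24L, 45L, 68L, 92L),
    season    = c("early", "early", "early", "late", "late"),
    analysis  = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Ordinal study day of a timestamp
#'
#' Day 1 is 1 June of the timestamp's own year; timestamps are interpreted in
#' UTC.
#'
#' @param timestamp POSIXct vector.
#' @return Integer vector of study days (can be < 1 or > 92 outside the
#'   season).
#' @export
study_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  jun1 <- as.POSIXct(sprintf("%04d-06-01", lt$year + 1900), tz = "UTC")
  as.integer(floor(as.numeric(difftime(timestamp, jun1, units = "days"))) + 1L)
}

#' Label points with their behavioural period
#'
#' Adds `day` (ordinal study day) and `period` columns. Points falling in the
#' calendar gaps (16-28 Jul, 8-15 Aug) or outside 1 Jun - 31 Aug are dropped.
#' Calving points are kept and labelled, with an `analysis_excluded` flag set,
#' since forage selection is not assessed during calving.
#'
#' @param points Data frame with a POSIXct `timestamp` column.
#' @param calendar A calendar from [period_calendar()].
#' @return The labelled, filtered data frame; the number of dropped gap rows
#'   is attached as attribute `"n_gap_dropped"`.
#' @export
assign_periods <- function(points, calendar = period_calendar()) {
  stopifnot(is.data.frame(points), "timestamp" %in% names(points))
  day <- study_day(points$timestamp)
  idx <- findInterval(day, calendar$start_day)
  period <- rep(NA_character_, length(day))
  ok <- idx >= 1L
  in_period <- ok & day <= calendar$end_day[pmax(idx, 1L)]
  period[in_period] <- calendar$period[idx[in_period]]
  out <- points
  out$day <- day
  out$period <- period
  keep <- !is.na(period)
  res <- out[keep, , drop = FALSE]
  res$analysis_excluded <- !calendar$analysis[match(res$period, calendar$period)]
  attr(res, "n_gap_dropped") <- sum(!keep)
  rownames(res) <- NULL
  res
}

#' Periods analysed for forage selection
#'
#' @param calendar A calendar from [period_calendar()].
#' @return Character vector of period names with `analysis = TRUE`.
#' @export
analysis_periods <- function(calendar = period_calendar()) {
  calendar$period[calendar$analysis]
}
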