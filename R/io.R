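#' Write a forage stack to plain-text files
#'
#' Grids are written as long-format CSV (one row per cell-week for the
#' weekly layers, one per cell for the static grids) with a YAML sidecar
#' recording the grid geometry — a plain-text equivalent of a banded raster
#' container.
#'
#' @param stack A `forage_stack`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_forage_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nx <- stack$nx; ny <- stack$ny; nw <- stack$n_weeks
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  weekly <- do.call(rbind, lapply(seq_len(nw), function(w) data.frame(
    week = w, ix = ix, iy = iy,
    biomass = as.vector(stack$biomass[, , w]),
    dn = as.vector(stack$dn[, , w]),
    de = as.vector(stack$de[, , w]),
    valid = as.vector(stack$valid[, , w])
  )))
  utils::write.csv(weekly, file.path(dir, "forage_weekly.csv"), row.names = FALSE)
  static <- data.frame(
    ix = ix, iy = iy,
    elevation = as.vector(stack$elevation),
    snowmelt = as.vector(stack$snowmelt),
    aspect = as.vector(stack$aspect),
    ocean = as.vector(stack$ocean),
    prediction_area = as.vector(stack$prediction_area)
  )
  utils::write.csv(static, file.path(dir, "static_grids.csv"), row.names = FALSE)
  yaml::write_yaml(
    list(nx = nx, ny = ny, cell_size = stack$cell_size, n_weeks = nw,
         origin = c(0, 0), registration = "cell-centre, half-open intervals",
         units = list(biomass = "g/m2 DM", dn = "g/100 g DM", de = "kJ/g DM",
                      elevation = "m", snowmelt = "ordinal day")),
    file.path(dir, "grids.yaml")
  )
  invisible(dir)
}

#' Read a forage stack written by [write_forage_stack()]
#'
#' @param dir Directory holding `forage_weekly.csv`, `static_grids.csv` and
#'   `grids.yaml`.
#' @return A `forage_stack` (without a generator config).
#' @export
read_forage_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "grids.yaml"))
  weekly <- utils::read.csv(file.path(dir, "forage_weekly.csv"))
  static <- utils::read.csv(file.path(dir, "static_grids.csv"))
  nx <- meta$nx; ny <- meta$ny; nw <- meta$n_weeks
  arr <- function(col) {
    a <- array(NA_real_, c(nx, ny, nw))
    a[cbind(weekly$ix, weekly$iy, weekly$week)] <- weekly[[col]]
    a
  }
  valid <- array(TRUE, c(nx, ny, nw))
  valid[cbind(weekly$ix, weekly$iy, weekly$week)] <- weekly$valid
  m2 <- function(col, fun = as.numeric) {
    m <- matrix(fun(NA), nx, ny)
    m[cbind(static$ix, static$iy)] <- fun(static[[col]])
    m
  }
  aspect <- m2("aspect", as.character)
  structure(
    list(biomass = arr("biomass"), dn = arr("dn"), de = arr("de"),
         valid = valid, elevation = m2("elevation"), snowmelt = m2("snowmelt"),
         aspect = aspect, ocean = m2("ocean", as.logical),
         prediction_area = m2("prediction_area", as.logical),
         nx = nx, ny = ny, cell_size = meta$cell_size, n_weeks = nw,
         n_clamped = NA_integer_, config = NULL),
    class = "forage_stack"
  )
}

#' Write telemetry points as CSV
#'
#' Columns: `animal_year_id`, `timestamp_iso8601` (UTC), `x`, `y`.
#'
#' @param locations Data frame of fixes.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_locations_csv <- function(locations, path) {
  out <- data.frame(
    animal_year_id = locations$animal_year_id,
    timestamp_iso8601 = format(locations$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = locations$x, y = locations$y
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read telemetry points from CSV
#'
#' @param path CSV written by [write_locations_csv()] (or any table with
#'   `animal_year_id`, `timestamp_iso8601`, `x`, `y`).
#' @return Data frame with a parsed POSIXct `timestamp` column.
#' @export
read_locations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  d
}
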