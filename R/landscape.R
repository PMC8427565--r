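#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the structure the analysis assumes: weekly 250 m
#' grids of forage biomass, digestible nitrogen (DN) and digestible energy
#' (DE) over a 92-day season (1 Jun - 31 Aug), with snow/cloud missingness
#' heaviest in early June, a coast-to-inland phenology gradient, static
#' elevation/aspect/snowmelt grids, an ocean strip along the coast edge, and
#' a forage prediction-area mask. Seasonal mean curves follow the observed
#' shapes: biomass rises to a peak in early August then declines; DN peaks
#' early, declines through the summer and crosses 1 g/100 g DM in mid July;
#' DE rises early then plateaus above 9 kJ/g DM.
#'
#' @param grid_nx,grid_ny Cell counts (>= 10).
#' @param cell_size Cell edge, metres (250 m to match the forage grids).
#' @param n_weeks Weekly layers across the season (>= 13; day d maps to week
#'   `min(ceiling(d/7), n_weeks)`).
#' @param coast_edge Which edge is coast: "N", "S", "E" or "W".
#' @param missingness_schedule Per-week fraction of masked (snow/cloud) cells
#'   in \[0, 1\]; default is heavy early-June snow, a mid-summer minimum and a
#'   late-August cloud rise.
#' @param coast_delay_days Phenology delay at the coast relative to the
#'   inland edge, days.
#' @param ocean_frac Fraction of the coast-edge rows that are ocean.
#' @param pred_exclude_frac Fraction of land cells excluded from the forage
#'   prediction area (emulating unsampled vegetation types), chosen as
#'   spatially coherent blobs.
#' @param smooth_bandwidth Gaussian smoothing bandwidth of the spatial noise
#'   fields, in cells.
#' @param curves Named list of seasonal curve parameters (see defaults).
#' @param noise Named list of spatial/weekly noise scales.
#' @param heatwave Unused here (see [weather_config()]).
#' @param seed Integer seed.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_nx = 60, grid_ny = 60, cell_size = 250,
                             n_weeks = 14, coast_edge = "N",
                             missingness_schedule = NULL,
                             coast_delay_days = 10,
                             ocean_frac = 0.08,
                             pred_exclude_frac = 0.10,
                             smooth_bandwidth = 3,
                             curves = NULL, noise = NULL,
                             heatwave = NULL,
                             seed = 1L) {
  if (is.null(missingness_schedule)) {
    base <- c(0.45, 0.35, 0.2, 0.1, 0.08, 0.06, 0.05, 0.05, 0.06, 0.08, 0.1, 0.15, 0.2, 0.2)
    missingness_schedule <- if (n_weeks <= length(base)) base[seq_len(n_weeks)] else
      c(base, rep(0.2, n_weeks - length(base)))
  }
  defaults_curves <- list(
    biomass = list(base = 5, peak = 30, peak_day = 65, width = 25),
    dn      = list(lo = 0.55, hi = 2.3, mid_day = 34, rate = 10,
                   bump = 0.12, bump_day = 6, bump_sd = 4),
    de      = list(lo = 8.6, rise = 2.6, mid_day = 12, rate = 6)
  )
  defaults_noise <- list(
    biomass_spatial = 0.25, biomass_week = 0.8,
    dn_spatial = 0.18, dn_week = 0.05,
    de_spatial = 0.35, de_week = 0.08,
    elev_spatial = 80, snowmelt_spatial = 3
  )
  cfg <- list(
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    cell_size = cell_size, n_weeks = as.integer(n_weeks),
    coast_edge = match.arg(coast_edge, c("N", "S", "E", "W")),
    missingness_schedule = missingness_schedule,
    coast_delay_days = coast_delay_days,
    ocean_frac = ocean_frac, pred_exclude_frac = pred_exclude_frac,
    smooth_bandwidth = smooth_bandwidth,
    curves = utils::modifyList(defaults_curves, curves %||% list()),
    noise = utils::modifyList(defaults_noise, noise %||% list()),
    seed = as.integer(seed)
  )
  validate_landscape_config(cfg)
  structure(cfg, class = "landscape_config")
}

validate_landscape_config <- function(cfg) {
  if (cfg$grid_nx < 10 || cfg$grid_ny < 10) stopf("grid_nx and grid_ny must be >= 10")
  if (cfg$n_weeks < 13) stopf("n_weeks must be >= 13 to cover the 92-day season")
  if (length(cfg$missingness_schedule) != cfg$n_weeks) {
    stopf("missingness_schedule must have one entry per week (%d)", cfg$n_weeks)
  }
  if (any(cfg$missingness_schedule < 0 | cfg$missingness_schedule > 1)) {
    stopf("missingness fractions must lie in [0, 1]")
  }
  days <- 1:92
  if (all(biomass_curve(days, cfg$curves$biomass) <= 0)) {
    stopf("biomass curve is non-positive everywhere; check curve parameters")
  }
  if (all(dn_curve(days, cfg$curves$dn) <= 0)) {
    stopf("DN curve is non-positive everywhere; check curve parameters")
  }
  if (all(de_curve(days, cfg$curves$de) <= 0)) {
    stopf("DE curve is non-positive everywhere; check curve parameters")
  }
  invisible(cfg)
}

# Seasonal mean curves (ordinal study day -> expected layer value).
biomass_curve <- function(day, p) {
  p$base + p$peak * exp(-(day - p$peak_day)^2 / (2 * p$width^2))
}
dn_curve <- function(day, p) {
  p$lo + (p$hi - p$lo) * stats::plogis(-(day - p$mid_day) / p$rate) +
    p$bump * exp(-(day - p$bump_day)^2 / (2 * p$bump_sd^2))
}
de_curve <- function(day, p) {
  p$lo + p$rise * stats::plogis((day - p$mid_day) / p$rate)
}

# Gaussian-smoothed standard-normal field (nx x ny), unit variance.
smooth_field <- function(nx, ny, bandwidth) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (bandwidth <= 0) return(z)
  half <- max(1L, ceiling(2 * bandwidth))
  k <- stats::dnorm(seq(-half, half), sd = bandwidth)
  k <- k / sum(k)
  pad_filter <- function(m, kern) {
    # separable convolution with edge renormalisation
    conv1 <- function(v) {
      n <- length(v)
      out <- numeric(n)
      for (j in seq_along(kern)) {
        off <- j - half - 1L
        src <- seq_len(n) + off
        valid <- src >= 1 & src <= n
        out[valid] <- out[valid] + kern[j] * v[src[valid]]
      }
      wt <- numeric(n)
      for (j in seq_along(kern)) {
        off <- j - half - 1L
        src <- seq_len(n) + off
        valid <- src >= 1 & src <= n
        wt[valid] <- wt[valid] + kern[j]
      }
      out / wt
    }
    m <- apply(m, 2L, conv1)
    t(apply(m, 1L, conv1))
  }
  s <- pad_filter(z, k)
  s / stats::sd(as.vector(s))
}

# Normalised coast proximity per cell: 1 at the coast edge, 0 inland.
coastness_matrix <- function(nx, ny, coast_edge) {
  ix <- matrix(rep(seq_len(nx), ny), nx, ny)
  iy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  switch(coast_edge,
    N = (iy - 1) / (ny - 1),
    S = (ny - iy) / (ny - 1),
    E = (ix - 1) / (nx - 1),
    W = (nx - ix) / (nx - 1)
  )
}

#' Generate a synthetic weekly forage landscape
#'
#' Produces a `forage_stack`: weekly biomass/DN/DE layers with a validity
#' mask, plus static elevation, aspect, snowmelt-date, ocean and
#' prediction-area grids. Spatial structure is smoothed Gaussian noise on top
#' of deterministic coast/elevation gradients; phenology is delayed toward
#' the coast edge. Any negative forage draw is clamped to 0 (mirroring how
#' negative model predictions are assigned a 0 value). Per-week masked-cell
#' counts equal `round(fraction * n_cells)` exactly; early-season masking
#' preferentially hits late-snowmelt cells (persistent snow), later masking
#' is spatially random (cloud).
#'
#' @param config A [landscape_config()].
#' @return A `forage_stack` object: arrays `biomass`, `dn`, `de` (nx x ny x
#'   n_weeks, underlying truth, clamped at 0), logical `valid` of the same
#'   shape, matrices `elevation`, `snowmelt` (ordinal calendar day), factor
#'   matrix `aspect` (5 levels), logical `ocean` and `prediction_area`, and
#'   grid geometry.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  validate_landscape_config(config)
  set.seed(config$seed)
  nx <- config$grid_nx; ny <- config$grid_ny; nw <- config$n_weeks
  coast <- coastness_matrix(nx, ny, config$coast_edge)
  bw <- config$smooth_bandwidth
  s_bm <- smooth_field(nx, ny, bw)
  s_dn <- smooth_field(nx, ny, bw)
  s_de <- smooth_field(nx, ny, bw)
  s_el <- smooth_field(nx, ny, bw)
  s_sm <- smooth_field(nx, ny, bw)
  s_veg <- smooth_field(nx, ny, bw * 1.5)

  elevation <- pmax(600 * (1 - coast)^1.5 + config$noise$elev_spatial * s_el, 0)
  snowmelt <- round(148 + 12 * coast + 0.015 * elevation +
    config$noise$snowmelt_spatial * s_sm)
  aspect <- aspect_from_elevation(elevation, config$cell_size)

  # ocean strip along the coast edge
  ocean <- matrix(FALSE, nx, ny)
  n_strip <- ceiling(config$ocean_frac * switch(config$coast_edge,
    N = , S = ny, E = , W = nx))
  if (n_strip > 0) {
    switch(config$coast_edge,
      N = { ocean[, ny - seq_len(n_strip) + 1] <- TRUE },
      S = { ocean[, seq_len(n_strip)] <- TRUE },
      E = { ocean[nx - seq_len(n_strip) + 1, ] <- TRUE },
      W = { ocean[seq_len(n_strip), ] <- TRUE }
    )
  }
  prediction_area <- !ocean
  if (config$pred_exclude_frac > 0) {
    land <- which(!ocean)
    n_ex <- floor(config$pred_exclude_frac * length(land))
    if (n_ex > 0) {
      ord <- land[order(s_veg[land])]
      prediction_area[ord[seq_len(n_ex)]] <- FALSE
    }
  }

  mid_day <- pmin(7 * seq_len(nw) - 3, 92)
  delay <- config$coast_delay_days * coast
  biomass <- dn <- de <- array(NA_real_, c(nx, ny, nw))
  n_clamped <- 0L
  for (w in seq_len(nw)) {
    teff <- mid_day[w] - delay
    bm <- biomass_curve(teff, config$curves$biomass) *
      exp(config$noise$biomass_spatial * s_bm) +
      stats::rnorm(nx * ny, 0, config$noise$biomass_week)
    dnv <- dn_curve(teff, config$curves$dn) + config$noise$dn_spatial * s_dn +
      stats::rnorm(nx * ny, 0, config$noise$dn_week)
    dev <- de_curve(teff, config$curves$de) + config$noise$de_spatial * s_de +
      stats::rnorm(nx * ny, 0, config$noise$de_week)
    n_clamped <- n_clamped + sum(bm < 0) + sum(dnv < 0) + sum(dev < 0)
    biomass[, , w] <- pmax(bm, 0)
    dn[, , w] <- pmax(dnv, 0)
    de[, , w] <- pmax(dev, 0)
  }

  valid <- array(TRUE, c(nx, ny, nw))
  sm_rank <- rank(snowmelt, ties.method = "random")
  for (w in seq_len(nw)) {
    n_mask <- round(config$missingness_schedule[w] * nx * ny)
    if (n_mask > 0) {
      wts <- if (w <= 4) sm_rank^2 else rep(1, nx * ny)
      sel <- sample.int(nx * ny, n_mask, prob = wts)
      vslice <- valid[, , w]
      vslice[sel] <- FALSE
      valid[, , w] <- vslice
    }
  }

  structure(
    list(
      biomass = biomass, dn = dn, de = de, valid = valid,
      elevation = elevation, snowmelt = snowmelt, aspect = aspect,
      ocean = ocean, prediction_area = prediction_area,
      nx = nx, ny = ny, cell_size = config$cell_size, n_weeks = nw,
      n_clamped = n_clamped, config = config
    ),
    class = "forage_stack"
  )
}

# Aspect classes from the elevation surface: dominant downslope direction,
# "flat" where the gradient is weak. Factor levels are always the 5 classes.
aspect_from_elevation <- function(elevation, cell_size, flat_tol = 0.004) {
  nx <- nrow(elevation); ny <- ncol(elevation)
  gx <- elevation[pmin(seq_len(nx) + 1, nx), ] - elevation[pmax(seq_len(nx) - 1, 1), ]
  gy <- elevation[, pmin(seq_len(ny) + 1, ny)] - elevation[, pmax(seq_len(ny) - 1, 1)]
  gx <- gx / (2 * cell_size); gy <- gy / (2 * cell_size)
  slope <- sqrt(gx^2 + gy^2)
  ang <- atan2(-gy, -gx)  # downslope direction
  lab <- ifelse(slope < flat_tol, "flat",
    ifelse(ang > -pi / 4 & ang <= pi / 4, "east",
      ifelse(ang > pi / 4 & ang <= 3 * pi / 4, "north",
        ifelse(ang <= -pi / 4 & ang > -3 * pi / 4, "south", "west"))))
  # stored as a character matrix; accessors rebuild the 5-level factor
  matrix(lab, nx, ny)
}

aspect_levels <- c("north", "east", "south", "west", "flat")

#' @export
print.forage_stack <- function(x, ...) {
  cat(sprintf(
    "<forage_stack> %d x %d cells (%g m), %d weeks; %.1f%% prediction area; %d clamped draws\n",
    x$nx, x$ny, x$cell_size, x$n_weeks,
    100 * mean(x$prediction_area), x$n_clamped
  ))
  invisible(x)
}

#' Grid cell index of planar coordinates
#'
#' Cell-centre registration with half-open cell intervals: a point on a
#' shared edge belongs to the cell with the larger index. The grid origin is
#' (0, 0) at the lower-left corner.
#'
#' @param stack A `forage_stack`.
#' @param x,y Coordinates, metres.
#' @return Data frame with columns `ix`, `iy` (NA outside the grid).
#' @export
cell_index <- function(stack, x, y) {
  ix <- floor(x / stack$cell_size) + 1
  iy <- floor(y / stack$cell_size) + 1
  out <- data.frame(ix = as.integer(ix), iy = as.integer(iy))
  bad <- ix < 1 | ix > stack$nx | iy < 1 | iy > stack$ny
  out$ix[bad] <- NA_integer_
  out$iy[bad] <- NA_integer_
  out
}

# Centre coordinates of cells.
cell_center <- function(stack, ix, iy) {
  data.frame(x = (ix - 0.5) * stack$cell_size, y = (iy - 0.5) * stack$cell_size)
}

# Week containing ordinal study day d (1-indexed from 1 June), clamped to the
# stack's last week.
week_of_day <- function(day, n_weeks) {
  pmin(pmax(ceiling(day / 7), 1L), n_weeks)
}

#' Look up forage and habitat values at points
#'
#' Forage values come from the weekly layer containing each point's study
#' day. With `truth = FALSE` (the default) masked cell-weeks return `NA`,
#' mirroring the missingness of the NDVI-based forage predictions; with
#' `truth = TRUE` the generator's underlying values are returned (used only
#' by the trajectory simulator, which moves animals through the true
#' landscape).
#'
#' @param stack A `forage_stack`.
#' @param x,y Coordinates (metres).
#' @param day Ordinal study day vector.
#' @param truth Bypass the validity mask?
#' @return Data frame: `biomass`, `dn`, `de`, `elevation`, `snowmelt`,
#'   `aspect`, `valid`, `ix`, `iy`, `week`.
#' @export
forage_at <- function(stack, x, y, day, truth = FALSE) {
  ci <- cell_index(stack, x, y)
  if (anyNA(ci$ix)) {
    stopf("%d point(s) fall outside the landscape grid", sum(is.na(ci$ix)))
  }
  wk <- week_of_day(day, stack$n_weeks)
  i3 <- cbind(ci$ix, ci$iy, wk)
  i2 <- cbind(ci$ix, ci$iy)
  valid <- stack$valid[i3]
  out <- data.frame(
    biomass = stack$biomass[i3], dn = stack$dn[i3], de = stack$de[i3],
    elevation = stack$elevation[i2], snowmelt = as.numeric(stack$snowmelt[i2]),
    aspect = factor(stack$aspect[i2], levels = aspect_levels), valid = valid,
    ix = ci$ix, iy = ci$iy, week = wk
  )
  if (!truth) {
    out$biomass[!valid] <- NA_real_
    out$dn[!valid] <- NA_real_
    out$de[!valid] <- NA_real_
  }
  out
}

#' Prediction-area membership of points
#'
#' TRUE where a point lies inside the grid in a forage prediction-area cell
#' (which excludes the ocean).
#'
#' @param stack A `forage_stack`.
#' @param x,y Coordinates, metres.
#' @return Logical vector.
#' @export
in_prediction_area <- function(stack, x, y) {
  ci <- cell_index(stack, x, y)
  ok <- !is.na(ci$ix)
  res <- rep(FALSE, length(x))
  res[ok] <- stack$prediction_area[cbind(ci$ix[ok], ci$iy[ok])]
  res
}

#' Ocean mask as polygons
#'
#' Returns the stack's ocean strip as a list of convex polygons suitable for
#' [mcp_available_area()].
#'
#' @param stack A `forage_stack`.
#' @return List of 2-column vertex matrices (empty if no ocean).
#' @export
ocean_polygons <- function(stack) {
  if (!any(stack$ocean)) return(list())
  cs <- stack$cell_size
  ix <- which(stack$ocean, arr.ind = TRUE)
  # the ocean is a full strip along one edge; bound it with one rectangle
  x0 <- (min(ix[, 1]) - 1) * cs; x1 <- max(ix[, 1]) * cs
  y0 <- (min(ix[, 2]) - 1) * cs; y1 <- max(ix[, 2]) * cs
  list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}
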