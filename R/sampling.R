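#' Sample available locations at the landscape scale
#'
#' For each used location, draws `ratio` available locations uniformly over
#' the prediction-area cells inside the MCP availability polygon (cell chosen
#' uniformly among sampleable cells, position uniform within the cell), each
#' carrying the used location's timestamp, period and animal-year id.
#'
#' @param used_points Used locations (after [assign_periods()]).
#' @param area An [mcp_available_area()] polygon.
#' @param stack The `forage_stack` providing the prediction-area mask.
#' @param ratio Available points per used point (default 10).
#' @param seed Integer seed.
#' @return Data frame of used + available rows with a `used` column (1/0).
#' @export
sample_available_landscape <- function(used_points, area, stack, ratio = 10,
                                       seed = 1L) {
  stopifnot(inherits(area, "mcp_area"), inherits(stack, "forage_stack"))
  set.seed(seed)
  cells <- which(stack$prediction_area, arr.ind = TRUE)
  cc <- cell_center(stack, cells[, 1], cells[, 2])
  in_hull <- points_in_polygon(cc$x, cc$y, area$hull)
  cells <- cells[in_hull, , drop = FALSE]
  if (nrow(cells) == 0) stopf("no sampleable cells: prediction area and MCP do not overlap")
  n_used <- nrow(used_points)
  used <- used_points
  used$used <- 1L
  if (ratio <= 0) {
    return(used)
  }
  n_av <- n_used * ratio
  pick <- sample.int(nrow(cells), n_av, replace = TRUE)
  jx <- stats::runif(n_av, 0, stack$cell_size)
  jy <- stats::runif(n_av, 0, stack$cell_size)
  avail <- used_points[rep(seq_len(n_used), each = ratio), , drop = FALSE]
  avail$x <- (cells[pick, 1] - 1) * stack$cell_size + jx
  avail$y <- (cells[pick, 2] - 1) * stack$cell_size + jy
  avail$used <- 0L
  out <- rbind(used, avail)
  rownames(out) <- NULL
  out
}

#' Build used steps from consecutive telemetry fixes
#'
#' A step joins consecutive fixes of the same animal-year collected 2 h apart
#' (within `tol_s` seconds of tolerance for telemetry jitter); pairs spanning
#' longer gaps are skipped. Turning angle is measured against the previous
#' step's bearing (the first step of each contiguous run has a missing turn).
#' When a `stack` is supplied, steps ending outside the forage prediction
#' area are dropped, mirroring the retention rule of the step-selection
#' design.
#'
#' @param points Telemetry fixes sorted by animal-year and time, with
#'   `animal_year_id`, `timestamp`, `x`, `y`.
#' @param stack Optional `forage_stack` for the end-in-prediction-area
#'   filter.
#' @param tol_s Tolerance on the 2-hour interval, seconds (default 300).
#' @return Data frame of used steps: start/end coordinates and times,
#'   `length` (m), `turn` (radians in (-pi, pi\]), `stratum_id`, `day` and
#'   `period` of the end fix when present, `used = 1`.
#' @export
build_steps <- function(points, stack = NULL, tol_s = 300) {
  stopifnot(all(c("animal_year_id", "timestamp", "x", "y") %in% names(points)))
  ord <- order(points$animal_year_id, points$timestamp)
  p <- points[ord, , drop = FALSE]
  n <- nrow(p)
  if (n < 2) return(empty_steps())
  same <- p$animal_year_id[-n] == p$animal_year_id[-1]
  dt <- as.numeric(difftime(p$timestamp[-1], p$timestamp[-n], units = "secs"))
  ok <- same & abs(dt - 7200) <= tol_s
  i0 <- which(ok); i1 <- i0 + 1L
  if (length(i0) == 0) return(empty_steps())
  dx <- p$x[i1] - p$x[i0]; dy <- p$y[i1] - p$y[i0]
  bearing <- atan2(dy, dx)
  # previous step of the same contiguous run: the step starting at i0 - 1
  prev_pos <- match(i0 - 1L, i0)
  turn <- wrap_angle(bearing - bearing[prev_pos])
  steps <- data.frame(
    animal_year_id = p$animal_year_id[i0],
    t0 = p$timestamp[i0], t1 = p$timestamp[i1],
    x0 = p$x[i0], y0 = p$y[i0], x1 = p$x[i1], y1 = p$y[i1],
    length = sqrt(dx^2 + dy^2), bearing = bearing, turn = turn,
    used = 1L, stringsAsFactors = FALSE
  )
  steps$day <- study_day(steps$t1)
  if ("period" %in% names(p)) steps$period <- p$period[i1]
  if (!is.null(stack)) {
    keep <- in_prediction_area(stack, steps$x1, steps$y1)
    steps <- steps[keep, , drop = FALSE]
  }
  if (nrow(steps)) {
    steps$stratum_id <- paste0(steps$animal_year_id, "_s",
                               seq_len(nrow(steps)))
  } else {
    steps$stratum_id <- character(0)
  }
  rownames(steps) <- NULL
  steps
}

empty_steps <- function() {
  data.frame(
    animal_year_id = character(0), t0 = as.POSIXct(character(0), tz = "UTC"),
    t1 = as.POSIXct(character(0), tz = "UTC"),
    x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
    length = numeric(0), bearing = numeric(0), turn = numeric(0),
    used = integer(0), day = integer(0), stratum_id = character(0),
    stringsAsFactors = FALSE
  )
}

#' Fit a period-specific gamma step-length kernel
#'
#' Maximum-likelihood gamma fit to observed step lengths. Zero lengths are
#' replaced by half the minimum positive length before fitting (the gamma
#' density is undefined at zero); at least 30 steps are required and
#' zero-variance lengths are refused.
#'
#' @param steps Used steps from [build_steps()].
#' @param period Optional period filter (uses the `period` column).
#' @return List with `shape`, `scale`, `n`, `period`.
#' @export
fit_step_kernel <- function(steps, period = NULL) {
  x <- steps$length
  if (!is.null(period)) {
    stopifnot("period" %in% names(steps))
    x <- x[steps$period == period & !is.na(steps$period)]
  }
  x <- x[!is.na(x)]
  if (length(x) < 30) {
    stopf("need at least 30 steps to fit a step-length kernel (have %d)", length(x))
  }
  if (stats::sd(x) == 0) stopf("step lengths have zero variance; gamma MLE is undefined")
  if (any(x <= 0)) {
    floor_val <- min(x[x > 0]) / 2
    x[x <= 0] <- floor_val
  }
  # MLE via the profile score: log(shape) - digamma(shape) = log(mean) -
  # mean(log x), solved by uniroot; scale = mean / shape. Fitting on scaled
  # data keeps the root bracket well conditioned for metre-scale lengths.
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (s <= 0) stopf("step lengths have (numerically) zero variance; gamma MLE is undefined")
  f <- function(a) log(a) - digamma(a) - s
  a0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka initialisation
  lo <- a0 / 10; hi <- a0 * 10
  while (f(lo) < 0) lo <- lo / 10
  while (f(hi) > 0) hi <- hi * 10
  shape <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  list(shape = shape, scale = m / shape,
       n = length(x), period = period %||% "all")
}

#' Sample available steps with mask rejection
#'
#' For each used step, draws `ratio` available steps from the same starting
#' location with lengths from the fitted gamma kernel and uniform turning
#' angles (uniform absolute bearings). Endpoints landing in the ocean,
#' outside the forage prediction area or off the grid are redrawn up to
#' `max_tries` rounds; strata still incomplete after that are dropped whole,
#' with a warning. The stratum id binds each used step to its available
#' steps.
#'
#' @param steps Used steps (from [build_steps()]).
#' @param kernel A kernel from [fit_step_kernel()], or a named list of
#'   kernels keyed by period (with optional `"all"` fallback) when steps span
#'   periods.
#' @param stack The `forage_stack` providing the masks.
#' @param ratio Available steps per used step (default 10).
#' @param seed Integer seed.
#' @param max_tries Redraw rounds before dropping a stratum.
#' @return Data frame of used + available step rows sharing `stratum_id`;
#'   available rows have `used = 0` and `NA` turn.
#' @export
sample_available_steps <- function(steps, kernel, stack, ratio = 10, seed = 1L,
                                   max_tries = 100) {
  stopifnot(inherits(stack, "forage_stack"))
  set.seed(seed)
  n <- nrow(steps)
  if (n == 0 || ratio <= 0) return(steps)
  if (!is.null(kernel$shape)) kernel <- list(all = kernel)
  per <- if ("period" %in% names(steps)) steps$period else rep("all", n)
  shape <- vapply(per, function(p) (kernel[[p]] %||% kernel[["all"]])$shape, 0)
  scale <- vapply(per, function(p) (kernel[[p]] %||% kernel[["all"]])$scale, 0)

  idx <- rep(seq_len(n), each = ratio)
  m <- length(idx)
  len <- stats::rgamma(m, shape = shape[idx], scale = scale[idx])
  ang <- stats::runif(m, -pi, pi)
  ex <- steps$x0[idx] + len * cos(ang)
  ey <- steps$y0[idx] + len * sin(ang)
  ok <- in_prediction_area(stack, ex, ey)
  tries <- 0
  while (any(!ok) && tries < max_tries) {
    tries <- tries + 1
    bad <- which(!ok)
    l2 <- stats::rgamma(length(bad), shape = shape[idx[bad]], scale = scale[idx[bad]])
    a2 <- stats::runif(length(bad), -pi, pi)
    ex[bad] <- steps$x0[idx[bad]] + l2 * cos(a2)
    ey[bad] <- steps$y0[idx[bad]] + l2 * sin(a2)
    len[bad] <- l2
    ok[bad] <- in_prediction_area(stack, ex[bad], ey[bad])
  }
  drop_strata <- unique(idx[!ok])
  if (length(drop_strata)) {
    warning(sprintf("dropping %d stratum/strata whose available steps could not be placed inside the mask after %d tries",
                    length(drop_strata), max_tries), call. = FALSE)
  }
  avail <- steps[idx, , drop = FALSE]
  avail$x1 <- ex; avail$y1 <- ey
  avail$length <- len
  avail$bearing <- ang
  avail$turn <- NA_real_
  avail$used <- 0L
  keep_used <- !(seq_len(n) %in% drop_strata)
  out <- rbind(steps[keep_used, , drop = FALSE],
               avail[!(idx %in% drop_strata), , drop = FALSE])
  out <- out[order(out$stratum_id, -out$used), , drop = FALSE]
  rownames(out) <- NULL
  out
}
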