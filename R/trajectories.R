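#' Ground truth for the trajectory generator
#'
#' Records the true step-selection coefficients, the gamma step-length
#' kernel(s) and the movement response used to simulate telemetry, so that
#' downstream fits can be checked against known parameters. Coefficients act
#' on endpoint covariates standardised over the landscape's prediction-area
#' cell-weeks (quadratics are squares of the standardised linear term,
#' matching the fitting convention); the scaling is recorded in the object
#' when trajectories are simulated.
#'
#' @param beta_ssf Named numeric vector of selection coefficients; names from
#'   `biomass`, `biomass_sq`, `dn`, `de`, `elevation`, `snowmelt`.
#' @param step_kernel Either `list(shape =, scale =)` applied to all periods,
#'   or a named list of such lists keyed by period with an `"all"` fallback.
#'   Shape/scale must be positive; lengths are metres.
#' @param beta_move Multiplier on the log kernel scale per unit mosquito
#'   index (movement-rate response to harassment); 0 disables it.
#' @param seed Integer seed recorded with the truth.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(beta_ssf = c(biomass = 0.5, biomass_sq = -0.3, dn = 0.66,
                                   de = 0.66, elevation = -0.5),
                      step_kernel = list(shape = 1.6, scale = 450),
                      beta_move = 0, seed = 1L) {
  allowed <- c("biomass", "biomass_sq", "dn", "de", "elevation", "snowmelt")
  if (is.null(names(beta_ssf)) || !all(names(beta_ssf) %in% allowed)) {
    stopf("beta_ssf must be named from: %s", paste(allowed, collapse = ", "))
  }
  if (!is.null(step_kernel$shape)) step_kernel <- list(all = step_kernel)
  for (k in step_kernel) {
    if (k$shape <= 0 || k$scale <= 0) stopf("step_kernel shape and scale must be > 0")
  }
  structure(
    list(beta_ssf = beta_ssf, step_kernel = step_kernel,
         beta_move = beta_move, seed = as.integer(seed)),
    class = "sim_truth"
  )
}

# Kernel for a period, falling back to "all".
kernel_for_period <- function(truth, period) {
  truth$step_kernel[[period]] %||% truth$step_kernel[["all"]] %||%
    stopf("no step kernel defined for period '%s' and no 'all' fallback", period)
}

# Landscape standardisation used by the generator: mean/sd of each covariate
# over prediction-area cell-weeks (underlying truth values).
landscape_scaling <- function(stack, covars) {
  pa <- as.vector(stack$prediction_area)
  grab <- function(v) {
    if (v %in% c("biomass", "dn", "de")) {
      m <- apply(stack[[v]], 3L, function(s) as.vector(s)[pa])
      as.vector(m)
    } else {
      as.vector(stack[[if (v == "elevation") "elevation" else "snowmelt"]])[pa]
    }
  }
  base <- setdiff(unique(sub("_sq$", "", covars)), character(0))
  data.frame(
    term = base,
    mean = vapply(base, function(v) mean(grab(v)), 0),
    sd = vapply(base, function(v) stats::sd(grab(v)), 0),
    row.names = NULL
  )
}

#' Simulate caribou trajectories by a step-selection process
#'
#' Each animal-year starts at a random prediction-area cell centre and takes
#' 2-hour steps. At every step, `n_candidates` endpoints are proposed from
#' the period's gamma step-length kernel with uniform turning angles
#' (implemented as uniform absolute bearings); proposals landing in the
#' ocean, outside the prediction area or off the grid are redrawn (up to
#' `max_tries` rounds, after which a degenerate mask is reported as an
#' error). One endpoint is then chosen with probability proportional to
#' `exp(beta_ssf . z)` where `z` are the endpoint covariates standardised
#' over the landscape. The chooser sees the generator's underlying forage
#' values: masking is an observation process, not a movement constraint.
#'
#' @param truth A [sim_truth()].
#' @param stack A [generate_landscape()] result.
#' @param weather Optional [generate_weather()] field; required when
#'   `truth$beta_move != 0` (kernel scale is multiplied by
#'   `exp(beta_move * MI)` at the current location/hour).
#' @param n_animal_years Number of animal-year tracks.
#' @param fixes_per_animal Fixes per track (steps = fixes - 1).
#' @param seed Integer seed.
#' @param start_day Ordinal study day of the first fix.
#' @param n_candidates Candidate endpoints per step.
#' @param max_tries Redraw rounds before declaring the mask degenerate.
#' @param year Calendar year for timestamps (UTC).
#' @param diagnostics Record running means of covariates at chosen vs
#'   proposed endpoints?
#' @return A `telemetry_sim` list: `locations` (animal_year_id, timestamp,
#'   x, y), `truth` (with the scaling manifest attached as `$scaling`), and
#'   optionally `diagnostics`.
#' @export
simulate_trajectories <- function(truth, stack, weather = NULL,
                                  n_animal_years = 10, fixes_per_animal = 120,
                                  seed = 1L, start_day = 1, n_candidates = 30,
                                  max_tries = 100, year = 2017L,
                                  diagnostics = FALSE) {
  stopifnot(inherits(truth, "sim_truth"), inherits(stack, "forage_stack"))
  if (truth$beta_move != 0 && is.null(weather)) {
    stopf("beta_move != 0 requires a weather field")
  }
  set.seed(seed)
  covars <- names(truth$beta_ssf)
  scaling <- landscape_scaling(stack, covars)
  truth$scaling <- scaling
  cal <- period_calendar()

  # standardised covariate matrix for arbitrary endpoints
  endpoint_z <- function(x, y, day) {
    f <- forage_at(stack, x, y, day, truth = TRUE)
    z <- matrix(0, length(x), length(covars), dimnames = list(NULL, covars))
    for (v in covars) {
      base <- sub("_sq$", "", v)
      row <- scaling[scaling$term == base, ]
      zb <- (f[[base]] - row$mean) / row$sd
      z[, v] <- if (grepl("_sq$", v)) zb^2 else zb
    }
    z
  }

  pa_cells <- which(stack$prediction_area, arr.ind = TRUE)
  if (nrow(pa_cells) == 0) stopf("prediction area is empty")
  start_idx <- pa_cells[sample.int(nrow(pa_cells), n_animal_years, replace = TRUE), , drop = FALSE]
  cx <- (start_idx[, 1] - 0.5) * stack$cell_size
  cy <- (start_idx[, 2] - 0.5) * stack$cell_size

  t0 <- as.POSIXct(sprintf("%04d-06-01 00:00:00", year), tz = "UTC") +
    (start_day - 1) * 86400
  n_steps <- fixes_per_animal - 1L
  X <- matrix(NA_real_, n_animal_years, fixes_per_animal)
  Y <- matrix(NA_real_, n_animal_years, fixes_per_animal)
  X[, 1] <- cx; Y[, 1] <- cy

  diag_sum_used <- diag_sum_prop <- stats::setNames(numeric(length(covars)), covars)
  diag_n_used <- diag_n_prop <- 0

  for (s in seq_len(n_steps)) {
    t_cur <- t0 + (s - 1) * 7200
    day <- study_day(t_cur + 7200)  # covariates at the endpoint's time
    pidx <- findInterval(day, cal$start_day)
    period <- if (pidx >= 1 && day <= cal$end_day[pidx]) cal$period[pidx] else "all"
    kern <- kernel_for_period(truth, period)
    scale_eff <- rep(kern$scale, n_animal_years)
    if (truth$beta_move != 0) {
      pts <- data.frame(x = X[, s], y = Y[, s],
                        timestamp = rep(t_cur, n_animal_years))
      mi <- attribute_insects(pts, weather, periods_only = FALSE)$mi
      scale_eff <- kern$scale * exp(truth$beta_move * mi)
    }
    K <- n_candidates
    len <- matrix(stats::rgamma(n_animal_years * K, shape = kern$shape,
                                scale = rep(scale_eff, K)), n_animal_years, K)
    ang <- matrix(stats::runif(n_animal_years * K, -pi, pi), n_animal_years, K)
    ex <- X[, s] + len * cos(ang)
    ey <- Y[, s] + len * sin(ang)
    ok <- matrix(in_prediction_area(stack, as.vector(ex), as.vector(ey)),
                 n_animal_years, K)
    tries <- 0
    while (any(!ok)) {
      tries <- tries + 1
      if (tries > max_tries) {
        stopf("could not place candidate endpoints inside the prediction area after %d rounds: degenerate mask", max_tries)
      }
      bad <- which(!ok)
      nb <- length(bad)
      row_i <- ((bad - 1) %% n_animal_years) + 1
      l2 <- stats::rgamma(nb, shape = kern$shape, scale = scale_eff[row_i])
      a2 <- stats::runif(nb, -pi, pi)
      ex[bad] <- X[row_i, s] + l2 * cos(a2)
      ey[bad] <- Y[row_i, s] + l2 * sin(a2)
      ok[bad] <- in_prediction_area(stack, ex[bad], ey[bad])
    }
    z <- endpoint_z(as.vector(ex), as.vector(ey), day)
    u <- matrix(z %*% truth$beta_ssf, n_animal_years, K)
    u <- u - apply(u, 1, max)
    p <- exp(u); p <- p / rowSums(p)
    pick <- apply(p, 1, function(pr) sample.int(K, 1L, prob = pr))
    sel <- cbind(seq_len(n_animal_years), pick)
    X[, s + 1] <- ex[sel]
    Y[, s + 1] <- ey[sel]
    if (diagnostics) {
      sel_flat <- (pick - 1) * n_animal_years + seq_len(n_animal_years)
      diag_sum_used <- diag_sum_used + colSums(z[sel_flat, , drop = FALSE])
      diag_sum_prop <- diag_sum_prop + colSums(z)
      diag_n_used <- diag_n_used + n_animal_years
      diag_n_prop <- diag_n_prop + n_animal_years * K
    }
  }

  ids <- sprintf("ay%03d", seq_len(n_animal_years))
  locations <- data.frame(
    animal_year_id = rep(ids, each = fixes_per_animal),
    timestamp = rep(t0 + (seq_len(fixes_per_animal) - 1) * 7200, n_animal_years),
    x = as.vector(t(X)), y = as.vector(t(Y)),
    stringsAsFactors = FALSE
  )
  out <- list(locations = locations, truth = truth,
              n_animal_years = n_animal_years,
              fixes_per_animal = fixes_per_animal, seed = as.integer(seed))
  if (diagnostics) {
    out$diagnostics <- list(
      mean_z_used = diag_sum_used / diag_n_used,
      mean_z_proposed = diag_sum_prop / diag_n_prop
    )
  }
  structure(out, class = "telemetry_sim")
}

#' @export
print.telemetry_sim <- function(x, ...) {
  cat(sprintf(
    "<telemetry_sim> %d animal-years x %d fixes (2 h); beta_ssf: %s\n",
    x$n_animal_years, x$fixes_per_animal,
    paste(sprintf("%s=%.2g", names(x$truth$beta_ssf), x$truth$beta_ssf), collapse = ", ")
  ))
  invisible(x)
}
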