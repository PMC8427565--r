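# Shared fixtures and independent oracles. Everything is generated in code;
# fixtures are deliberately small so whole-suite runtime stays modest.

tiny_landscape <- function(seed = 11, nx = 40, ny = 40,
                           missingness = rep(0.05, 14), ...) {
  generate_landscape(landscape_config(
    grid_nx = nx, grid_ny = ny, seed = seed,
    missingness_schedule = missingness, ...
  ))
}

tiny_weather <- function(stack, seed = 5, ...) {
  generate_weather(weather_config(stack$config, ...), seed = seed)
}

# Simulate telemetry and build a standardized SSF design table, scaled with
# the generator's landscape manifest so fitted coefficients are directly
# comparable to the simulation truth.
ssf_design_from_sim <- function(truth, stack, n_animal_years, fixes_per_animal,
                                seed, start_day = 16, ratio = 10) {
  sim <- simulate_trajectories(truth, stack,
    n_animal_years = n_animal_years,
    fixes_per_animal = fixes_per_animal,
    seed = seed, start_day = start_day
  )
  pts <- assign_periods(sim$locations)
  pts$used <- 1L
  steps <- build_steps(pts, stack)
  kern <- fit_step_kernel(steps)
  strata <- suppressWarnings(
    sample_available_steps(steps, kern, stack, ratio = ratio,
                           seed = seed + 1)
  )
  rows <- attribute_covariates(strata, stack)
  std <- standardize_covariates(
    rows,
    cols = c("biomass", "dn", "de", "elevation", "step_length"),
    manifest = sim$truth$scaling[, c("term", "mean", "sd")]
  )
  list(rows = std$rows, manifest = std$manifest, sim = sim, kern = kern)
}

# --- independent oracles -------------------------------------------------

# Conditional-logit log-likelihood by direct enumeration over strata.
oracle_clogit_loglik <- function(beta, X, y, stratum) {
  eta <- drop(X %*% beta)
  sum(vapply(split(seq_along(y), stratum), function(ix) {
    eta[ix][y[ix] == 1] - log(sum(exp(eta[ix])))
  }, 0))
}

# Marginal mixed-logit log-likelihood by dense trapezoid integration of the
# random intercept, group by group.
oracle_mixed_loglik_dense <- function(beta, sigma, X, y, group,
                                      lim = 8, n_grid = 20001) {
  eta0 <- drop(X %*% beta)
  b <- seq(-lim * sigma, lim * sigma, length.out = n_grid)
  db <- b[2] - b[1]
  total <- 0
  for (ix in split(seq_along(y), group)) {
    ll_b <- vapply(b, function(bb) {
      e <- eta0[ix] + bb
      sum(y[ix] * e - log1p(exp(e)))
    }, 0)
    lg <- ll_b + stats::dnorm(b, 0, sigma, log = TRUE)
    m <- max(lg)
    total <- total + m + log(sum(exp(lg - m)) * db)
  }
  total
}

# Simple generalised least squares for a balanced one-way random-intercept
# model at a fixed variance ratio lambda = sigma_u^2 / sigma_e^2.
oracle_gls_beta <- function(X, y, group, lambda) {
  V <- diag(length(y))
  for (ix in split(seq_along(y), group)) {
    V[ix, ix] <- V[ix, ix] + lambda
  }
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

# Rayleigh test statistic for circular uniformity: returns the p-value
# approximation exp(-n * Rbar^2).
rayleigh_p <- function(angles) {
  n <- length(angles)
  rbar2 <- (mean(cos(angles))^2 + mean(sin(angles))^2)
  z <- n * rbar2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# Used points drawn from the RSF model itself: cells sampled proportional to
# exp(beta . z) over the prediction area, z standardised over prediction-area
# cell-weeks (the generator's landscape scaling). The independence sample is
# the data-generating process the landscape RSF assumes, so fitted
# coefficients are directly comparable to beta.
make_rsf_used <- function(stack, beta, n_ay, n_per, days = 16:40, seed = 1) {
  set.seed(seed)
  scaling <- caribouforage:::landscape_scaling(stack, names(beta))
  cells <- which(stack$prediction_area, arr.ind = TRUE)
  cc <- data.frame(x = (cells[, 1] - 0.5) * stack$cell_size,
                   y = (cells[, 2] - 0.5) * stack$cell_size)
  # per-day cell selection weights, computed once
  W <- vapply(days, function(d) {
    f <- forage_at(stack, cc$x, cc$y, rep(d, nrow(cc)), truth = TRUE)
    z <- vapply(names(beta), function(v) {
      base <- sub("_sq$", "", v)
      row <- scaling[scaling$term == base, ]
      zb <- (f[[base]] - row$mean) / row$sd
      if (grepl("_sq$", v)) zb^2 else zb
    }, numeric(nrow(cc)))
    u <- drop(z %*% beta)
    exp(u - max(u))
  }, numeric(nrow(cc)))
  n <- n_ay * n_per
  dd <- sample(days, n, replace = TRUE)
  pick <- integer(n)
  for (j in seq_along(days)) {
    ix <- which(dd == days[j])
    if (length(ix)) {
      pick[ix] <- sample.int(nrow(cc), length(ix), replace = TRUE,
                             prob = W[, j])
    }
  }
  t0 <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC")
  res <- data.frame(
    animal_year_id = rep(sprintf("r%03d", seq_len(n_ay)), each = n_per),
    x = cc$x[pick], y = cc$y[pick],
    timestamp = t0 + (dd - 1) * 86400 + sample(0:11, n, replace = TRUE) * 7200
  )
  res <- assign_periods(res)
  attr(res, "scaling") <- scaling
  res
}
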