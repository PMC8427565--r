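ts_utc <- function(s) as.POSIXct(s, tz = "UTC")

test_that("period assignment follows the calendar with its gaps", {
  pts <- data.frame(timestamp = ts_utc(c(
    "2017-06-20 10:00", "2017-07-20 10:00", "2017-08-31 23:59",
    "2017-06-05 08:00", "2017-07-10 00:00", "2017-08-10 12:00",
    "2017-07-29 00:00"
  )))
  out <- assign_periods(pts)
  expect_equal(attr(out, "n_gap_dropped"), 2)  # 20 Jul and 10 Aug
  expect_equal(out$period[out$day == 20], "post_calving")
  expect_equal(out$period[out$day == 92], "end_of_summer")
  expect_equal(out$period[out$day == 5], "calving")
  expect_equal(out$period[out$day == 40], "mosquito")
  expect_equal(out$period[out$day == 59], "oestrid")
  # calving is labelled but flagged out of the selection analyses
  expect_true(out$analysis_excluded[out$period == "calving"])
  expect_false(any(out$analysis_excluded[out$period != "calving"]))
  expect_false("calving" %in% analysis_periods())
})

test_that("period intervals are disjoint and the gaps belong to no period", {
  cal <- period_calendar()
  days <- unlist(Map(seq, cal$start_day, cal$end_day))
  expect_false(any(duplicated(days)))
  expect_true(all(setdiff(1:92, days) == c(46:58, 69:76)))
})

test_that("MCP area handles hulls, ocean removal and degenerate input", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  m <- mcp_available_area(sq)
  expect_equal(m$area, 1.0)
  # top half ocean: polygon difference leaves half the hull
  ocean <- cbind(c(-1, 2, 2, -1), c(0.5, 0.5, 2, 2))
  m2 <- mcp_available_area(sq, ocean = ocean)
  expect_equal(m2$area, 0.5)
  # interior points do not change the hull
  m3 <- mcp_available_area(rbind(sq, data.frame(x = 0.5, y = 0.5)))
  expect_equal(m3$area, 1.0)
  expect_equal(nrow(m3$hull), 4)
  expect_error(mcp_available_area(data.frame(x = c(0, 1, 2), y = c(0, 1, 2))),
               "collinear")
})

test_that("landscape availability sampling is a 10:1 design with shared timestamps", {
  st <- tiny_landscape(seed = 4, nx = 30, ny = 30)
  used <- data.frame(
    animal_year_id = rep(c("a1", "a2"), each = 50),
    timestamp = ts_utc("2017-06-20 00:00") + seq_len(100) * 7200,
    x = runif(100, 2000, 5000), y = runif(100, 2000, 5000)
  )
  used <- assign_periods(used)
  mcp <- mcp_available_area(used, ocean = ocean_polygons(st))
  out <- sample_available_landscape(used, mcp, st, ratio = 10, seed = 3)
  expect_equal(sum(out$used == 0), 10 * nrow(used))
  expect_equal(sum(out$used == 1), nrow(used))
  # every timestamp occurs 11 times: 1 used + 10 available
  expect_true(all(table(out$timestamp) == 11))
  # every available timestamp appears among used rows
  expect_true(all(out$timestamp[out$used == 0] %in% out$timestamp[out$used == 1]))
  # available points respect the masks; membership is cell-level, so the
  # sampled cell's centre must lie in the hull
  av <- out[out$used == 0, ]
  expect_true(all(in_prediction_area(st, av$x, av$y)))
  ci <- cell_index(st, av$x, av$y)
  cc <- (cbind(ci$ix, ci$iy) - 0.5) * st$cell_size
  expect_true(all(points_in_polygon(cc[, 1], cc[, 2], mcp$hull)))
  # ratio 0 and seeding behave as documented
  expect_equal(sum(sample_available_landscape(used, mcp, st, 0, 1)$used == 0), 0)
  again <- sample_available_landscape(used, mcp, st, ratio = 10, seed = 3)
  expect_identical(out$x, again$x)
})

test_that("available landscape points are uniform over sampleable cells", {
  st <- tiny_landscape(seed = 6, nx = 20, ny = 20)
  used <- data.frame(
    animal_year_id = "a1",
    timestamp = ts_utc("2017-07-01 00:00") + (1:10000) * 7200,
    x = runif(10000, 100, 4900), y = runif(10000, 100, 4900)
  )
  used$period <- "mosquito"
  corners <- data.frame(animal_year_id = "a1",
                        timestamp = ts_utc("2017-07-01 00:00"),
                        x = c(10, 4990, 4990, 10), y = c(10, 10, 4990, 4990),
                        period = "mosquito")
  mcp <- mcp_available_area(corners)  # whole grid, so cell weights are equal
  out <- sample_available_landscape(used, mcp, st, ratio = 10, seed = 8)
  av <- out[out$used == 0, ]
  ci <- cell_index(st, av$x, av$y)
  counts <- table(factor(paste(ci$ix, ci$iy),
                         levels = apply(which(st$prediction_area, arr.ind = TRUE),
                                        1, paste, collapse = " ")))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("step construction skips gaps and measures geometry correctly", {
  t0 <- ts_utc("2017-06-20 00:00")
  pts <- data.frame(
    animal_year_id = "a1",
    timestamp = t0 + c(0, 2, 6) * 3600,   # 2 h pair then a 4 h gap
    x = c(0, 300, 900), y = c(0, 400, 900)
  )
  pts <- assign_periods(pts)
  s <- build_steps(pts)
  expect_equal(nrow(s), 1)
  expect_equal(s$length, 500)  # 3-4-5 triangle
  # collinear motion has zero turning angle on the second step
  pts2 <- data.frame(
    animal_year_id = "a1", timestamp = t0 + c(0, 2, 4) * 3600,
    x = c(0, 100, 200), y = c(0, 100, 200)
  )
  s2 <- build_steps(pts2)
  expect_equal(nrow(s2), 2)
  expect_true(is.na(s2$turn[1]))
  expect_equal(s2$turn[2], 0)
  # timestamp jitter within the tolerance still pairs fixes
  pts3 <- data.frame(
    animal_year_id = "a1", timestamp = t0 + c(0, 7200 + 200), x = 0:1, y = 0:1
  )
  expect_equal(nrow(build_steps(pts3)), 1)
  expect_equal(nrow(build_steps(pts3, tol_s = 100)), 0)
})

test_that("steps ending outside the prediction area are dropped", {
  st <- tiny_landscape(seed = 4, nx = 20, ny = 20, ocean_frac = 0.3,
                       pred_exclude_frac = 0)
  t0 <- ts_utc("2017-06-20 00:00")
  ocean_y <- (st$ny - 1) * st$cell_size  # coast edge N: top rows are ocean
  pts <- data.frame(
    animal_year_id = "a1", timestamp = t0 + (0:2) * 7200,
    x = c(500, 600, 700), y = c(500, ocean_y, 600)
  )
  s <- build_steps(pts, st)
  expect_equal(nrow(s), 1)  # the step into the ocean is gone
  expect_equal(s$y1, 600)
})

test_that("gamma kernel MLE recovers parameters and refuses degenerate input", {
  set.seed(77)
  x <- rgamma(1e5, shape = 2, scale = 300)
  k <- fit_step_kernel(data.frame(length = x))
  expect_lt(abs(k$shape - 2) / 2, 0.05)
  expect_lt(abs(k$scale - 300) / 300, 0.05)
  expect_error(fit_step_kernel(data.frame(length = rgamma(10, 2, 1))),
               "at least 30")
  expect_error(fit_step_kernel(data.frame(length = rep(500, 50))), "zero variance")
  # zero lengths are floored at half the minimum positive length
  y <- c(rep(0, 5), rgamma(100, shape = 2, scale = 300))
  expect_silent(k2 <- fit_step_kernel(data.frame(length = y)))
  expect_gt(k2$shape, 0)
  # periods are fitted independently
  d <- data.frame(length = c(rgamma(50, 2, scale = 100), rgamma(50, 5, scale = 50)),
                  period = rep(c("p1", "p2"), each = 50))
  k_a <- fit_step_kernel(d, "p1"); k_b <- fit_step_kernel(d, "p2")
  expect_false(isTRUE(all.equal(k_a$shape, k_b$shape)))
})

test_that("available steps form complete strata inside the mask", {
  st <- tiny_landscape(seed = 10, nx = 30, ny = 30)
  tr <- sim_truth(beta_ssf = c(dn = 0.3), step_kernel = list(shape = 2, scale = 300))
  sim <- simulate_trajectories(tr, st, n_animal_years = 5,
                               fixes_per_animal = 41, seed = 3)
  pts <- sim$locations; pts$used <- 1L
  steps <- build_steps(pts, st)
  kern <- fit_step_kernel(steps)
  out <- sample_available_steps(steps, kern, st, ratio = 10, seed = 5)
  expect_equal(nrow(out), 11 * nrow(steps))
  counts <- table(out$stratum_id, out$used)
  expect_true(all(counts[, "1"] == 1))
  expect_true(all(counts[, "0"] == 10))
  av <- out[out$used == 0, ]
  expect_true(all(in_prediction_area(st, av$x1, av$y1)))
  # available steps share the used step's start
  expect_true(all(av$x0 %in% steps$x0))
})

test_that("available turning angles are uniform on the circle", {
  st <- generate_landscape(landscape_config(
    grid_nx = 60, grid_ny = 60, seed = 2, ocean_frac = 0, pred_exclude_frac = 0,
    missingness_schedule = rep(0, 14)))
  n <- 10000
  steps <- data.frame(
    animal_year_id = "a1",
    x0 = runif(n, 5000, 10000), y0 = runif(n, 5000, 10000),
    x1 = 0, y1 = 0, length = 0, bearing = 0, turn = NA, used = 1L,
    t0 = ts_utc("2017-07-01") , t1 = ts_utc("2017-07-01 02:00"),
    day = 31, stratum_id = paste0("s", 1:n)
  )
  kern <- list(shape = 2, scale = 200)
  out <- sample_available_steps(steps, kern, st, ratio = 10, seed = 4)
  av <- out[out$used == 0, ]
  ang <- atan2(av$y1 - av$y0, av$x1 - av$x0)
  expect_gt(rayleigh_p(ang), 0.01)
})

test_that("strata that cannot be placed are dropped with a warning", {
  cfg <- landscape_config(grid_nx = 20, grid_ny = 20, seed = 1,
                          ocean_frac = 0, pred_exclude_frac = 0)
  st <- generate_landscape(cfg)
  st$prediction_area[] <- FALSE
  st$prediction_area[10, 10] <- TRUE
  steps <- data.frame(
    animal_year_id = "a1", x0 = 2375, y0 = 2375, x1 = 2375, y1 = 2375,
    length = 10, bearing = 0, turn = NA, used = 1L,
    t0 = ts_utc("2017-07-01"), t1 = ts_utc("2017-07-01 02:00"),
    day = 31, stratum_id = "s1"
  )
  kern <- list(shape = 2, scale = 50000)  # essentially never lands in the cell
  expect_warning(out <- sample_available_steps(steps, kern, st, ratio = 10,
                                               seed = 2, max_tries = 3),
                 "dropping")
  expect_equal(nrow(out), 0)
})
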