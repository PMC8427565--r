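#' Forage adequacy flags
#'
#' Flags whether forage meets the physiological thresholds for female
#' caribou: digestible nitrogen below 1 g N/100 g DM or digestible energy
#' below 9 kJ/g DM likely impairs them (they cannot compensate for poor
#' quality with increased intake). Values exactly at a threshold are
#' adequate (the impairing region is strictly below).
#'
#' @param rows Data frame with `dn` and/or `de` columns (raw units).
#' @param dn_threshold g N/100 g DM (default 1).
#' @param de_threshold kJ/g DM (default 9).
#' @return `rows` with logical `protein_adequate` and `energy_adequate`
#'   columns appended.
#' @export
adequacy_flags <- function(rows, dn_threshold = 1, de_threshold = 9) {
  if (dn_threshold <= 0 || de_threshold <= 0) stopf("thresholds must be > 0")
  if (!is.null(rows$dn)) rows$protein_adequate <- rows$dn >= dn_threshold
  if (!is.null(rows$de)) rows$energy_adequate <- rows$de >= de_threshold
  rows
}

#' Seasonal forage adequacy summary
#'
#' Reports, from a landscape's weekly layers, the first ordinal study day
#' whose spatial-mean DN (over valid prediction-area cells) drops below the
#' protein threshold, plus the per-week spatial means of all three forage
#' components.
#'
#' @param stack A `forage_stack`.
#' @param dn_threshold g N/100 g DM (default 1).
#' @return List with `first_day_dn_below` (NA if never) and a per-week data
#'   frame `weekly_means`.
#' @export
adequacy_summary <- function(stack, dn_threshold = 1) {
  pa <- stack$prediction_area
  wk_mean <- function(arr) {
    vapply(seq_len(stack$n_weeks), function(w) {
      sl <- arr[, , w]
      ok <- pa & stack$valid[, , w]
      mean(sl[ok])
    }, 0)
  }
  wm <- data.frame(
    week = seq_len(stack$n_weeks),
    biomass = wk_mean(stack$biomass),
    dn = wk_mean(stack$dn),
    de = wk_mean(stack$de)
  )
  days <- 1:92
  dn_daily <- wm$dn[week_of_day(days, stack$n_weeks)]
  below <- which(dn_daily < dn_threshold)
  list(
    first_day_dn_below = if (length(below)) min(below) else NA_integer_,
    weekly_means = wm
  )
}

#' End-to-end run configuration
#'
#' Collects every knob of a full synthetic analysis run. Defaults follow the
#' study design: 10 available points per used location, 10 available steps
#' per used step, 5-fold / 10-bin / 10-repeat cross-validation, adequacy
#' thresholds of 1 g N/100 g DM and 9 kJ/g DM, and a collinearity screen at
#' `|r| > 0.7`.
#'
#' @param seed Master seed (stage seeds are derived from it).
#' @param landscape A [landscape_config()].
#' @param weather A [weather_config()] (built from `landscape` if `NULL`).
#' @param truth A [sim_truth()].
#' @param n_animal_years,fixes_per_animal Telemetry dimensions.
#' @param ratio_landscape,ratio_patch Availability ratios.
#' @param cv List with `k`, `bins`, `repeats`, or `NULL` to skip
#'   cross-validation.
#' @param dn_threshold,de_threshold Adequacy thresholds.
#' @param collinearity_threshold Screen threshold on `|r|`.
#' @param nodes Quadrature nodes for RSF fits.
#' @param write_grids Also write the weekly grids as CSV?
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       landscape = landscape_config(seed = seed),
                       weather = NULL,
                       truth = sim_truth(seed = seed),
                       n_animal_years = 20, fixes_per_animal = 1104,
                       ratio_landscape = 10, ratio_patch = 10,
                       cv = list(k = 5, bins = 10, repeats = 10),
                       dn_threshold = 1, de_threshold = 9,
                       collinearity_threshold = 0.7,
                       nodes = 15, write_grids = FALSE) {
  structure(
    list(seed = as.integer(seed), landscape = landscape,
         weather = weather %||% weather_config(landscape),
         truth = truth, n_animal_years = n_animal_years,
         fixes_per_animal = fixes_per_animal,
         ratio_landscape = ratio_landscape, ratio_patch = ratio_patch,
         cv = cv, dn_threshold = dn_threshold, de_threshold = de_threshold,
         collinearity_threshold = collinearity_threshold,
         nodes = nodes, write_grids = write_grids),
    class = "run_config"
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates landscape, weather and telemetry, then runs the complete
#' analysis per analysed period (post-calving, mosquito, oestrid, end of
#' summer; calving is labelled but excluded): landscape-scale RSF candidate
#' set with AIC table, patch-scale SSF candidate set with QIC table,
#' insect-stage candidate sets for the insect periods, cross-validation of
#' the top models, and movement-rate model ladders for the insect periods.
#' All tables are written as CSV into `out_dir`, along with a YAML manifest
#' recording the configuration, the simulation ground truth and a config
#' hash; outputs are byte-identical under the same seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress with row counts?
#' @return Invisibly, a list of in-memory results mirroring the files.
#' @export
run_all <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t_start <- Sys.time()
  hash <- config_hash(unclass(config))

  say("stage simulate: landscape %dx%d, %d animal-years",
      config$landscape$grid_nx, config$landscape$grid_ny, config$n_animal_years)
  stack <- generate_landscape(config$landscape)
  weather <- generate_weather(config$weather, seed = derive_seed(config$seed, 1))
  sim <- simulate_trajectories(
    config$truth, stack, weather,
    n_animal_years = config$n_animal_years,
    fixes_per_animal = config$fixes_per_animal,
    seed = derive_seed(config$seed, 2)
  )
  pts <- assign_periods(sim$locations)
  say("stage periods: %d fixes labelled, %d dropped in calendar gaps",
      nrow(pts), attr(pts, "n_gap_dropped"))

  mcp <- mcp_available_area(pts, ocean = ocean_polygons(stack))
  results <- list(config = config, hash = hash, truth = sim$truth, mcp = mcp)
  adequacy <- adequacy_summary(stack, config$dn_threshold)
  utils::write.csv(adequacy$weekly_means,
                   file.path(out_dir, "forage_weekly_means.csv"), row.names = FALSE)

  periods <- analysis_periods()
  missingness <- list()
  cvs <- list()
  for (per in periods) {
    used_p <- pts[pts$period == per & !pts$analysis_excluded, , drop = FALSE]
    if (nrow(used_p) < 30) {
      say("stage %s: only %d used fixes; period skipped", per, nrow(used_p))
      next
    }
    # ---- landscape scale ----
    ua <- sample_available_landscape(used_p, mcp, stack,
                                     ratio = config$ratio_landscape,
                                     seed = derive_seed(config$seed, 10 + match(per, periods)))
    rows <- attribute_covariates(ua, stack, weather)
    missingness[[paste0("landscape_", per)]] <- attr(rows, "missingness")
    std <- standardize_covariates(rows)
    flags <- collinearity_screen(std$rows, config$collinearity_threshold,
                                 cols = c("biomass", "dn", "de", "elevation", "snowmelt"))
    cands <- build_candidate_set(per, "landscape", flagged = flags)
    fits <- lapply(cands, function(sp) fit_rsf_mixed(std$rows, sp, nodes = config$nodes))
    tab <- delta_and_weights(fits, "aic")
    utils::write.csv(cbind(tab, config_hash = hash),
                     file.path(out_dir, sprintf("rsf_selection_%s.csv", per)),
                     row.names = FALSE)
    top_i <- which.max(vapply(fits, function(f) -aic(f), 0))
    top_fit <- fits[[top_i]]
    utils::write.csv(coef_table(top_fit),
                     file.path(out_dir, sprintf("rsf_top_coefs_%s.csv", per)),
                     row.names = FALSE)
    say("stage rsf %s: %d rows, top = %s", per, nrow(std$rows), tab$label[1])

    insect <- switch(per, mosquito = "mi", oestrid = "oi", NULL)
    if (!is.null(insect) && top_fit$spec$base) {
      icands <- build_insect_candidate_set(top_fit$spec, insect)
      ifits <- lapply(icands, function(sp) fit_rsf_mixed(std$rows, sp, nodes = config$nodes))
      itab <- delta_and_weights(ifits, "aic")
      utils::write.csv(cbind(itab, config_hash = hash),
                       file.path(out_dir, sprintf("rsf_insect_selection_%s.csv", per)),
                       row.names = FALSE)
    }
    if (!is.null(config$cv)) {
      cvs[[paste0("landscape_", per)]] <- kfold_cv(
        std$rows, top_fit$spec, k = config$cv$k, bins = config$cv$bins,
        repeats = config$cv$repeats, nodes = config$nodes,
        seed = derive_seed(config$seed, 30 + match(per, periods))
      )
    }

    # ---- patch scale ----
    steps_used <- build_steps(pts[pts$period == per, , drop = FALSE], stack)
    if (nrow(steps_used) >= 30) {
      kern <- fit_step_kernel(steps_used)
      strata <- sample_available_steps(steps_used, kern, stack,
                                       ratio = config$ratio_patch,
                                       seed = derive_seed(config$seed, 50 + match(per, periods)))
      srows <- attribute_covariates(strata, stack, weather)
      missingness[[paste0("patch_", per)]] <- attr(srows, "missingness")
      sstd <- standardize_covariates(srows)
      sflags <- collinearity_screen(sstd$rows, config$collinearity_threshold,
                                    cols = c("biomass", "dn", "de", "elevation", "snowmelt"))
      scands <- build_candidate_set(per, "patch", flagged = sflags)
      sfits <- lapply(scands, function(sp) fit_ssf_clogit(sstd$rows, sp))
      stab <- delta_and_weights(sfits, "qic")
      utils::write.csv(cbind(stab, config_hash = hash),
                       file.path(out_dir, sprintf("ssf_selection_%s.csv", per)),
                       row.names = FALSE)
      stop_i <- which.max(vapply(sfits, function(f) -qic(f), 0))
      utils::write.csv(coef_table(sfits[[stop_i]]),
                       file.path(out_dir, sprintf("ssf_top_coefs_%s.csv", per)),
                       row.names = FALSE)
      say("stage ssf %s: %d strata, top = %s", per,
          sfits[[stop_i]]$n_strata, stab$label[1])
      if (!is.null(config$cv) && !is.null(sfits[[stop_i]]$spec)) {
        cvs[[paste0("patch_", per)]] <- kfold_cv(
          sstd$rows, sfits[[stop_i]]$spec, k = config$cv$k,
          bins = config$cv$bins, repeats = config$cv$repeats,
          seed = derive_seed(config$seed, 70 + match(per, periods))
        )
      }

      if (!is.null(insect)) {
        msteps <- attribute_covariates(steps_used, stack, weather)
        msteps <- msteps[!is.na(msteps[[insect]]), , drop = FALSE]
        if (nrow(msteps) >= 30 && stats::sd(msteps[[insect]]) > 0) {
          mv <- select_movement_model(msteps, insect)
          utils::write.csv(cbind(mv$table, config_hash = hash),
                           file.path(out_dir, sprintf("movement_selection_%s.csv", per)),
                           row.names = FALSE)
          best <- mv$fits[[which.min(vapply(mv$fits, aic, 0))]]
          utils::write.csv(coef_table(best, robust = FALSE),
                           file.path(out_dir, sprintf("movement_top_coefs_%s.csv", per)),
                           row.names = FALSE)
          results[[paste0("movement_", per)]] <- mv
        }
      }
      results[[paste0("ssf_", per)]] <- list(table = stab, fits = sfits)
    }
    results[[paste0("rsf_", per)]] <- list(table = tab, fits = fits)
  }

  miss_df <- do.call(rbind, Map(function(nm, df) cbind(stage = nm, df),
                                names(missingness), missingness))
  if (!is.null(miss_df)) {
    utils::write.csv(miss_df, file.path(out_dir, "missingness_report.csv"),
                     row.names = FALSE)
  }
  cv_df <- do.call(rbind, Map(function(nm, cv) data.frame(
    model = nm, mean_rs = cv$mean_rs,
    min_repeat = min(cv$per_repeat, na.rm = TRUE),
    max_repeat = max(cv$per_repeat, na.rm = TRUE)
  ), names(cvs), cvs))
  if (!is.null(cv_df)) {
    utils::write.csv(cv_df, file.path(out_dir, "cv_summary.csv"), row.names = FALSE)
  }

  if (config$write_grids) write_forage_stack(stack, file.path(out_dir, "grids"))
  write_locations_csv(sim$locations, file.path(out_dir, "locations.csv"))
  manifest <- list(
    config_hash = hash,
    seed = config$seed,
    truth = list(
      beta_ssf = as.list(config$truth$beta_ssf),
      step_kernel = config$truth$step_kernel,
      beta_move = config$truth$beta_move
    ),
    scaling = if (!is.null(sim$truth$scaling)) {
      stats::setNames(
        Map(function(m, s) list(mean = m, sd = s),
            sim$truth$scaling$mean, sim$truth$scaling$sd),
        sim$truth$scaling$term
      )
    },
    first_day_dn_below = adequacy$first_day_dn_below,
    thresholds = list(dn = config$dn_threshold, de = config$de_threshold),
    n_animal_years = config$n_animal_years
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  say("run complete in %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  results$cv <- cvs
  results$missingness <- miss_df
  invisible(results)
}
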