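#' Movement-rate mixed model on log step length
#'
#' Linear mixed model of log-transformed step length on an insect activity
#' index and ordinal study day (a nuisance capturing the seasonal movement
#' pattern), with a random intercept per animal-year. Continuous predictors
#' are standardised and quadratic terms are squares of the standardised
#' linear terms; the scaling manifest is stored for effect-size
#' computations. Variance components are estimated by REML (the single
#' variance ratio is profiled out, as in lme4); the ML log-likelihood is
#' also recorded and feeds AIC so that models with different fixed effects
#' are comparable.
#'
#' @param steps Used steps carrying `length`, `animal_year_id`, `day`, and
#'   the insect index column (`mi` or `oi`).
#' @param terms Term vector over `mi`/`oi`, `mi_sq`/`oi_sq`, `od`, `od_sq`
#'   (see [movement_candidates()]).
#' @param label Optional label for selection tables.
#' @return A `move_fit`: `coefficients`, `se`, `vcov`, `sigma_u`, `sigma_e`,
#'   `logLik` (REML), `logLik_ml`, `k`, `n`, `manifest`, `converged`.
#' @export
fit_move_lmm <- function(steps, terms, label = NULL) {
  insect_col <- intersect(c("mi", "oi"), sub("_sq$", "", terms))
  need <- unique(c(insect_col, "od"))
  d <- data.frame(animal_year_id = steps$animal_year_id,
                  length = steps$length, od = as.numeric(steps$day))
  for (cc in insect_col) d[[cc]] <- steps[[cc]]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (any(d$length <= 0)) {
    stopf("non-positive step lengths; apply the kernel floor before the log transform")
  }
  if (length(unique(d$animal_year_id)) < 2) stopf("need at least 2 animal-years")
  for (cc in need) {
    if (stats::sd(d[[cc]]) == 0) {
      stopf("covariate '%s' is constant; coefficient inestimable, spec rejected", cc)
    }
  }
  std <- standardize_covariates(d, cols = need)
  d <- std$rows
  d$log_len <- log(d$length)
  fml <- stats::as.formula(paste("log_len ~", paste(terms, collapse = " + "),
                                 "+ (1 | animal_year_id)"))
  # boundary variance fits emit optimiser chatter; convergence is recorded
  # from optinfo instead
  fit <- suppressMessages(suppressWarnings(lme4::lmer(fml, data = d, REML = TRUE)))
  fit_ml <- suppressMessages(suppressWarnings(lme4::refitML(fit)))
  b <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  vcm <- lme4::VarCorr(fit)
  structure(
    list(coefficients = b, se = sqrt(diag(vc)), vcov = vc,
         sigma_u = attr(vcm$animal_year_id, "stddev")[[1]],
         sigma_e = stats::sigma(fit),
         logLik = as.numeric(stats::logLik(fit)),
         logLik_ml = as.numeric(stats::logLik(fit_ml)),
         k = length(b) + 2,  # fixed effects + RI variance + residual variance
         n = nrow(d), manifest = std$manifest,
         converged = isTRUE(fit@optinfo$conv$opt == 0) &&
           !any(grepl("failed to converge",
                      fit@optinfo$conv$lme4$messages %||% character(0))),
         terms = terms, label = label %||% paste(terms, collapse = " + "),
         model = fit),
    class = "move_fit"
  )
}

#' @export
print.move_fit <- function(x, ...) {
  cat(sprintf("<move_fit> n=%d, sigma_u=%.3f, sigma_e=%.3f, AIC(ML)=%.2f\n",
              x$n, x$sigma_u, x$sigma_e, aic(x)))
  print(data.frame(beta = x$coefficients, se = x$se))
  invisible(x)
}

#' Fit and rank the movement-model candidate ladder
#'
#' @param steps Used steps with the insect index attributed.
#' @param insect `"mi"` or `"oi"`.
#' @return List with `fits` and the AIC selection `table`.
#' @export
select_movement_model <- function(steps, insect = c("mi", "oi")) {
  insect <- match.arg(insect)
  cands <- movement_candidates(insect)
  fits <- lapply(seq_along(cands), function(i) {
    f <- fit_move_lmm(steps, cands[[i]], label = names(cands)[i])
    f$spec <- list(label = names(cands)[i])
    f
  })
  list(fits = fits, table = delta_and_weights(fits, "aic"))
}

#' Harassment effect on movement rate
#'
#' Fold-change of the median step length between two values of the insect
#' index, holding ordinal day fixed (its terms cancel in the contrast of
#' linear predictors, so the ratio is evaluated at any fixed day; the study
#' convention is the period median). Computed as
#' `exp(lp(index_high) - lp(index_low))` on the model's standardised scale.
#'
#' @param fit A `move_fit`.
#' @param index_low,index_high Raw index values in \[0, 1\].
#' @return Fold-change (1 under a null insect effect).
#' @export
harassment_ratio <- function(fit, index_low, index_high) {
  if (index_low < 0 || index_low > 1 || index_high < 0 || index_high > 1) {
    stopf("index values must lie in [0, 1]")
  }
  insect <- intersect(c("mi", "oi"), sub("_sq$", "", fit$terms))
  if (!length(insect)) return(1)
  row <- fit$manifest[fit$manifest$term == insect, ]
  zl <- (index_low - row$mean) / row$sd
  zh <- (index_high - row$mean) / row$sd
  b <- fit$coefficients
  lin <- if (insect %in% names(b)) b[[insect]] else 0
  qd <- if (paste0(insect, "_sq") %in% names(b)) b[[paste0(insect, "_sq")]] else 0
  delta <- lin * (zh - zl) + qd * (zh^2 - zl^2)
  unname(exp(delta))
}
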