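#' Attribute forage, habitat and insect covariates
#'
#' Attaches covariates to use-availability locations or to steps (at their
#' endpoints, along with step length). Forage values come from the weekly
#' layer containing each row's study day; rows whose forage cell-week is
#' masked (snow/cloud) are dropped and the dropped fraction is reported per
#' period via the `"missingness"` attribute, mirroring the reporting of
#' unpredictable locations in the source analysis. Static habitat (elevation,
#' aspect, snowmelt date) is always attributed. Points outside the landscape
#' grid are an error, never a silent drop.
#'
#' @param x Locations (with `x`, `y`, `day`) or steps (with `x1`, `y1`,
#'   `length`).
#' @param stack A `forage_stack`.
#' @param weather Optional `weather_field`; when given, `mi`/`oi` are
#'   attributed within their insect periods.
#' @return Design rows: `response` (used flag), covariates, grouping ids;
#'   attribute `"missingness"` holds the per-period dropped fractions.
#' @export
attribute_covariates <- function(x, stack, weather = NULL) {
  stopifnot(inherits(stack, "forage_stack"))
  is_steps <- all(c("x1", "y1") %in% names(x))
  px <- if (is_steps) x$x1 else x$x
  py <- if (is_steps) x$y1 else x$y
  if (!"day" %in% names(x)) {
    if (!("t1" %in% names(x) || "timestamp" %in% names(x))) {
      stopf("rows need a 'day', 't1' or 'timestamp' column")
    }
    x$day <- study_day(if (is_steps) x$t1 else x$timestamp)
  }
  f <- forage_at(stack, px, py, x$day, truth = FALSE)
  out <- x
  out$biomass <- f$biomass
  out$dn <- f$dn
  out$de <- f$de
  out$elevation <- f$elevation
  out$snowmelt <- f$snowmelt
  out$aspect <- f$aspect
  if (is_steps) out$step_length <- x$length
  if (!is.null(weather)) {
    pts <- data.frame(x = px, y = py,
                      timestamp = if (is_steps) x$t1 else x$timestamp,
                      period = x$period %||% NA_character_)
    ins <- attribute_insects(pts, weather, periods_only = TRUE)
    out$mi <- ins$mi
    out$oi <- ins$oi
  }
  dropped <- !f$valid
  per <- out$period %||% rep("all", nrow(out))
  miss <- stats::aggregate(dropped, list(period = per), function(z)
    c(n = length(z), n_dropped = sum(z)))
  miss <- data.frame(period = miss$period, n = miss$x[, "n"],
                     n_dropped = miss$x[, "n_dropped"])
  miss$frac_dropped <- miss$n_dropped / miss$n
  res <- out[!dropped, , drop = FALSE]
  res$response <- res$used
  rownames(res) <- NULL
  attr(res, "missingness") <- miss
  res
}

#' Standardise continuous covariates
#'
#' Z-scores continuous covariates over the full fitting table (used and
#' available rows pooled), then builds quadratic columns as squares of the
#' standardised linear terms (`biomass_sq`, `elevation_sq`, `snowmelt_sq`,
#' and `mi_sq`/`oi_sq`/`od_sq` where present). The means and SDs are
#' returned as a manifest so that prediction-time data can be scaled with
#' the training scaling rather than re-centred on itself.
#'
#' @param rows Design rows.
#' @param cols Columns to standardise; defaults to the continuous covariates
#'   present among `biomass`, `dn`, `de`, `elevation`, `snowmelt`, `mi`,
#'   `oi`, `od`, `step_length`.
#' @param manifest Optional manifest from a previous call: reuse its
#'   means/SDs instead of recomputing (columns it does not cover are scaled
#'   on the data and appended).
#' @return List with `rows` (standardised, with `_sq` columns) and
#'   `manifest` (data frame `term`, `mean`, `sd`).
#' @export
standardize_covariates <- function(rows, cols = NULL, manifest = NULL) {
  if (is.null(cols)) {
    cols <- intersect(c("biomass", "dn", "de", "elevation", "snowmelt",
                        "mi", "oi", "od", "step_length"), names(rows))
    cols <- cols[vapply(cols, function(cc) !all(is.na(rows[[cc]])), TRUE)]
  }
  need <- if (is.null(manifest)) cols else setdiff(cols, manifest$term)
  if (length(need)) {
    mu <- vapply(need, function(cc) mean(rows[[cc]], na.rm = TRUE), 0)
    sd_ <- vapply(need, function(cc) stats::sd(rows[[cc]], na.rm = TRUE), 0)
    if (any(sd_ == 0 | is.na(sd_))) {
      stopf("zero-variance covariate(s): %s", paste(need[sd_ == 0 | is.na(sd_)], collapse = ", "))
    }
    manifest <- rbind(manifest[, c("term", "mean", "sd")],
                      data.frame(term = need, mean = unname(mu), sd = unname(sd_),
                                 stringsAsFactors = FALSE))
  }
  for (cc in cols) {
    row <- manifest[manifest$term == cc, ]
    rows[[cc]] <- (rows[[cc]] - row$mean) / row$sd
  }
  for (cc in intersect(c("biomass", "elevation", "snowmelt", "mi", "oi", "od"), cols)) {
    rows[[paste0(cc, "_sq")]] <- rows[[cc]]^2
  }
  list(rows = rows, manifest = manifest)
}

#' Screen covariate pairs for collinearity
#'
#' Pearson correlations between all continuous covariate pairs; pairs with
#' `|r|` strictly greater than the threshold are flagged so that candidate
#' models never contain both members (as when biomass and DE are strongly
#' negatively correlated late in the season). `|r|` exactly at the threshold
#' is acceptable (the acceptable region is `|r| <= threshold`).
#'
#' @param rows Design rows.
#' @param threshold Flagging threshold on `|r|` (default 0.7).
#' @param cols Columns to screen; defaults to the continuous linear terms
#'   present.
#' @return Data frame of flagged pairs (`var1`, `var2`, `r`); the full
#'   correlation matrix is attached as attribute `"cor"`.
#' @export
collinearity_screen <- function(rows, threshold = 0.7, cols = NULL) {
  if (is.null(cols)) {
    cols <- intersect(c("biomass", "dn", "de", "elevation", "snowmelt",
                        "mi", "oi", "step_length"), names(rows))
    cols <- cols[vapply(cols, function(cc) !all(is.na(rows[[cc]])), TRUE)]
  }
  if (nrow(rows) < 3) stopf("need at least 3 rows to screen correlations")
  cm <- stats::cor(rows[, cols, drop = FALSE], use = "pairwise.complete.obs")
  flagged <- data.frame(var1 = character(0), var2 = character(0), r = numeric(0),
                        stringsAsFactors = FALSE)
  if (length(cols) >= 2) {
    for (i in seq_len(length(cols) - 1)) {
      for (j in (i + 1):length(cols)) {
        if (!is.na(cm[i, j]) && abs(cm[i, j]) > threshold) {
          flagged <- rbind(flagged, data.frame(
            var1 = cols[i], var2 = cols[j], r = cm[i, j],
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  attr(flagged, "cor") <- cm
  flagged
}
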