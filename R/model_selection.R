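#' Build the forage candidate model set
#'
#' Enumerates the candidate structures compared within a period at one
#' scale: a null model, a base habitat model, and the base habitat model
#' plus every subset of the forage components, with biomass entering either
#' linearly or with a quadratic term (forage-maturation expectation). For
#' three available components this yields 13 candidates; any specification
#' containing a flagged collinear pair is removed (so when biomass and DE
#' are strongly correlated, they are never tested within the same model,
#' leaving 9).
#'
#' @param period Period label.
#' @param scale `"landscape"` or `"patch"`.
#' @param flagged Flagged pairs from [collinearity_screen()] (or `NULL`).
#' @param forage_components Available components (default biomass, DN, DE).
#' @return List of [model_spec()] objects.
#' @export
build_candidate_set <- function(period, scale = c("landscape", "patch"),
                                flagged = NULL,
                                forage_components = c("biomass", "dn", "de")) {
  scale <- match.arg(scale)
  specs <- list(
    model_spec(scale, period, base = FALSE, label = "Null"),
    model_spec(scale, period, base = TRUE)
  )
  nf <- length(forage_components)
  if (nf > 0) {
    for (m in 1:(2^nf - 1)) {
      subset <- forage_components[bitwAnd(m, 2^(seq_len(nf) - 1)) > 0]
      quad_opts <- if ("biomass" %in% subset) c(FALSE, TRUE) else FALSE
      for (q in quad_opts) {
        specs <- c(specs, list(model_spec(scale, period, forage = subset,
                                          biomass_quad = q)))
      }
    }
  }
  drop_flagged_specs(specs, flagged)
}

drop_flagged_specs <- function(specs, flagged) {
  if (is.null(flagged) || nrow(flagged) == 0) return(specs)
  keep <- vapply(specs, function(sp) {
    tm <- sp$forage
    !any(flagged$var1 %in% tm & flagged$var2 %in% tm)
  }, TRUE)
  specs[keep]
}

#' Build the insect-stage candidate set
#'
#' Given the period's top forage model, tests whether the insect index (MI
#' or OI) and its interactions with the forage components improve fit: the
#' forage model alone, plus the insect main effect with every subset of the
#' forage-component interactions (the biomass interaction carries the
#' quadratic interaction when the forage model has biomass^2). With three
#' forage components this yields 9 candidates.
#'
#' @param top_spec The top forage [model_spec()].
#' @param insect `"mi"` or `"oi"`.
#' @return List of model specs (first element is the forage model itself).
#' @export
build_insect_candidate_set <- function(top_spec, insect = c("mi", "oi")) {
  insect <- match.arg(insect)
  comp <- top_spec$forage
  specs <- list(top_spec)
  nf <- length(comp)
  for (m in 0:(2^nf - 1)) {
    subset <- if (nf > 0) comp[bitwAnd(m, 2^(seq_len(nf) - 1)) > 0] else character(0)
    specs <- c(specs, list(model_spec(
      top_spec$scale, top_spec$period, forage = comp,
      biomass_quad = top_spec$biomass_quad, insect = insect,
      insect_interactions = subset
    )))
  }
  specs
}

#' Akaike information criterion of a fit
#'
#' `AIC = -2 logLik + 2k`, with `k` the fit's parameter count (fixed effects
#' plus the random-intercept variance for mixed fits).
#'
#' @param fit An `rsf_fit`, `ssf_fit` or `move_fit`.
#' @return AIC value.
#' @export
aic <- function(fit) {
  ll <- if (!is.null(fit$logLik_ml)) fit$logLik_ml else fit$logLik
  -2 * ll + 2 * fit$k
}

#' Quasi-likelihood independence criterion for a clustered conditional fit
#'
#' `QIC = -2 logLik + 2 trace(A V_r)` where `A` is the observed information
#' of the independence (conditional-likelihood) fit and `V_r` the cluster
#' sandwich covariance. The trace penalty is computed from the uncorrected
#' sandwich meat so that the criterion reduces exactly to `-2 logLik + 2k`
#' when the robust and model-based covariances coincide.
#'
#' @param fit An `ssf_fit`.
#' @param meat Optional replacement meat matrix (diagnostics).
#' @return QIC value.
#' @export
qic <- function(fit, meat = NULL) {
  m <- meat %||% fit$meat
  tr <- sum(diag(solve(fit$info, m)))
  -2 * fit$logLik + 2 * tr
}

#' Rank a candidate set by an information criterion
#'
#' @param fits List of fitted candidates (same data).
#' @param criterion `"aic"` or `"qic"`.
#' @return A selection table (data frame): `label`, `logLik`, `k`, `ic`,
#'   `delta`, `weight`, sorted best-first; non-converged fits are excluded
#'   with a message.
#' @export
delta_and_weights <- function(fits, criterion = c("aic", "qic")) {
  criterion <- match.arg(criterion)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !isTRUE(f$divergent), TRUE)
  if (any(!ok)) {
    message(sprintf("excluding %d non-converged fit(s) from the selection table", sum(!ok)))
    fits <- fits[ok]
  }
  if (!length(fits)) stopf("no converged fits to rank")
  ic <- vapply(fits, if (criterion == "aic") aic else qic, 0)
  lab <- vapply(fits, function(f) {
    if (!is.null(f$spec)) f$spec$label else paste(f$terms, collapse = "+")
  }, "")
  ll <- vapply(fits, function(f) if (!is.null(f$logLik_ml)) f$logLik_ml else f$logLik, 0)
  k <- vapply(fits, function(f) f$k, 0)
  d <- ic - min(ic)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(label = lab, logLik = ll, k = k, ic = ic, delta = d,
                    weight = w, stringsAsFactors = FALSE)
  names(out)[names(out) == "ic"] <- criterion
  out[order(out[[criterion]]), , drop = FALSE]
}

#' Movement-model candidate ladder
#'
#' The six fixed-effect structures compared for step length during an insect
#' period: ordinal day (OD), OD + OD^2, and each crossed with the insect
#' index entering linearly or quadratically
#' (index, index + index^2).
#'
#' @param insect `"mi"` or `"oi"`.
#' @return List of term character vectors with labels as names.
#' @export
movement_candidates <- function(insect = c("mi", "oi")) {
  insect <- match.arg(insect)
  i1 <- insect; i2 <- paste0(insect, "_sq")
  I1 <- toupper(i1); I2 <- paste0(toupper(insect), "^2")
  out <- list(
    c(i1, i2, "od", "od_sq"),
    c(i1, "od", "od_sq"),
    c(i1, i2, "od"),
    c(i1, "od"),
    c("od", "od_sq"),
    c("od")
  )
  names(out) <- c(
    paste(I1, "+", I2, "+ OD + OD^2"),
    paste(I1, "+ OD + OD^2"),
    paste(I1, "+", I2, "+ OD"),
    paste(I1, "+ OD"),
    "OD + OD^2", "OD"
  )
  out
}
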