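#' Conditional logistic step-selection fit
#'
#' Maximises the conditional likelihood
#' `prod_s exp(b'x_used) / sum_j exp(b'x_j)` over strata (one used + R
#' available steps each) by Newton-Raphson with step-halving. Convergence
#' requires the maximum absolute score below `tol_score` and a relative
#' log-likelihood change below `tol_ll`. Naive standard errors come from the
#' inverse observed information; robust standard errors from a sandwich
#' whose scores are summed within animal-year clusters, with a G/(G-1)
#' small-sample correction (G = number of clusters). Strata whose used row
#' was lost (e.g. to forage masking) are removed whole before fitting.
#' Separation - a covariate direction along which the likelihood keeps
#' improving without bound - is detected and reported via the `divergent`
#' flag.
#'
#' @param rows Standardised design rows with `response`, `stratum_id`,
#'   `animal_year_id` and covariate columns.
#' @param spec A [model_spec()] (patch scale) or a character vector of
#'   terms.
#' @param cluster Column name holding the cluster id (default
#'   `"animal_year_id"`).
#' @param max_iter,tol_score,tol_ll Newton controls.
#' @return An `ssf_fit`: `coefficients`, `se` (naive), `robust_se`, `vcov`,
#'   `vcov_robust`, `logLik`, `k`, `n_strata`, `n_clusters`, `info` (observed
#'   information), `meat` (uncorrected cluster meat), `converged`,
#'   `divergent`, `terms`, `spec`.
#' @export
fit_ssf_clogit <- function(rows, spec, cluster = "animal_year_id",
                           max_iter = 50, tol_score = 1e-6, tol_ll = 1e-10) {
  terms <- if (inherits(spec, "model_spec")) spec_terms(spec) else spec
  stopifnot(all(c("response", "stratum_id") %in% names(rows)))
  # drop strata without exactly one used row
  used_per <- tapply(rows$response, rows$stratum_id, sum)
  n_per <- tapply(rows$response, rows$stratum_id, length)
  good <- names(used_per)[used_per == 1 & n_per >= 2]
  rows <- rows[rows$stratum_id %in% good, , drop = FALSE]
  if (nrow(rows) == 0) stopf("no complete strata (1 used + >=1 available) to fit")
  rows <- rows[order(rows$stratum_id), , drop = FALSE]
  X <- build_model_matrix(rows, terms, intercept = FALSE)
  y <- rows$response
  strat <- factor(rows$stratum_id)
  si <- as.integer(strat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stopf("design is rank deficient (rank %d < %d columns)", qx$rank, ncol(X))
  }
  p <- ncol(X)
  beta <- rep(0, p)

  loglik_parts <- function(beta) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) < 500) {
      # standardised covariates keep eta small: direct softmax is safe
      lse_row <- log(drop(rowsum(exp(eta), si)))[si]
    } else {
      # centred fallback for extreme linear predictors
      mx_row <- stats::ave(eta, si, FUN = max)
      lse_g <- log(drop(rowsum(exp(eta - mx_row), si)))
      mx_g <- mx_row[!duplicated(si)]                # rows are stratum-sorted
      lse_row <- (lse_g + mx_g)[si]
    }
    prob <- exp(eta - lse_row)
    list(ll = sum((eta - lse_row)[y == 1]), prob = prob)
  }

  lp <- loglik_parts(beta)
  ll <- lp$ll
  converged <- FALSE
  divergent <- FALSE
  for (it in seq_len(max_iter)) {
    pr <- lp$prob
    U <- drop(crossprod(X, y - pr))
    if (max(abs(U)) < tol_score) { converged <- TRUE; break }
    M <- rowsum(pr * X, si)
    A <- crossprod(X, pr * X) - crossprod(M)
    step <- tryCatch(solve(A, U), error = function(e) NULL)
    if (is.null(step)) { divergent <- TRUE; break }
    # step-halving
    ok <- FALSE
    for (h in 0:20) {
      beta_new <- beta + step / 2^h
      lp_new <- loglik_parts(beta_new)
      if (is.finite(lp_new$ll) && lp_new$ll >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    dl <- abs(lp_new$ll - ll) / (abs(ll) + 1e-10)
    beta <- beta_new; ll <- lp_new$ll; lp <- lp_new
    U_new <- drop(crossprod(X, y - lp$prob))
    if (max(abs(U_new)) < tol_score && dl < tol_ll) { converged <- TRUE; break }
    if (max(abs(beta)) > 15) { divergent <- TRUE; break }
  }
  # separation drives coefficients off to infinity while the score decays;
  # on standardised covariates any |beta| this large is a separation signal
  if (max(abs(beta)) > 15) divergent <- TRUE

  pr <- lp$prob
  M <- rowsum(pr * X, si)
  A <- crossprod(X, pr * X) - crossprod(M)
  vcov_naive <- tryCatch(solve(A), error = function(e) matrix(NA_real_, p, p))
  # per-stratum score residuals, summed into clusters
  S <- rowsum((y - pr) * X, si)
  cl <- tapply(rows[[cluster]], si, function(v) v[1])
  G <- rowsum(S, cl)
  n_cl <- nrow(G)
  meat <- crossprod(G)
  vcov_robust <- vcov_naive %*% meat %*% vcov_naive
  if (n_cl > 1) vcov_robust <- vcov_robust * n_cl / (n_cl - 1)
  dimnames(vcov_naive) <- dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  structure(
    list(
      coefficients = stats::setNames(beta, colnames(X)),
      se = sqrt(diag(vcov_naive)), robust_se = sqrt(diag(vcov_robust)),
      vcov = vcov_naive, vcov_robust = vcov_robust,
      logLik = ll, k = p, n_strata = nlevels(strat), n_rows = nrow(rows),
      n_clusters = n_cl, info = A, meat = meat,
      converged = converged, divergent = divergent,
      terms = colnames(X), spec = if (inherits(spec, "model_spec")) spec else NULL
    ),
    class = "ssf_fit"
  )
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("<ssf_fit> %d strata, %d clusters, logLik %.3f%s%s\n",
              x$n_strata, x$n_clusters, x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$divergent) " [DIVERGENT]" else ""))
  print(data.frame(beta = x$coefficients, se = x$se, robust_se = x$robust_se))
  invisible(x)
}

#' Coefficient table for a fitted selection model
#'
#' Mirrors the reporting layout of step-selection and RSF coefficient
#' tables: estimate, SE (robust at the patch scale), Wald p-value and 95%
#' confidence limits.
#'
#' @param fit An `ssf_fit` or `rsf_fit`.
#' @param robust Use robust SEs when available?
#' @return Data frame with `term`, `beta`, `se`, `p`, `l95`, `u95`.
#' @export
coef_table <- function(fit, robust = inherits(fit, "ssf_fit")) {
  se <- if (robust && !is.null(fit$robust_se)) fit$robust_se else fit$se
  b <- fit$coefficients
  z <- b / se
  data.frame(
    term = names(b), beta = unname(b), se = unname(se),
    p = unname(2 * stats::pnorm(-abs(z))),
    l95 = unname(b - 1.96 * se), u95 = unname(b + 1.96 * se),
    stringsAsFactors = FALSE
  )
}
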