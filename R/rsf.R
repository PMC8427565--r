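# Gauss-Hermite nodes/weights by the Golub-Welsch eigendecomposition of the
# Jacobi matrix (weight function exp(-x^2)).
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Mixed-effects logistic resource selection fit
#'
#' Fits the use-availability RSF as a Bernoulli-logit generalized linear
#' mixed model with one normal random intercept per animal-year, maximising
#' the marginal likelihood. The random effect is integrated out by adaptive
#' Gauss-Hermite quadrature: each group's integrand is re-centred at its
#' conditional mode (found by a per-group scalar Newton iteration) and
#' scaled by its curvature before applying the quadrature rule. The
#' marginal likelihood is maximised over (fixed effects, log sigma) by
#' L-BFGS-B with analytic Fisher-identity gradients (posterior-weighted
#' score sums); standard errors come from the numerically differentiated
#' observed information at the optimum. A boundary variance (sigma -> 0) is
#' reported via the `boundary` flag but the fit is still returned. With a
#' single group, or `var_fixed = 0`, the model reduces to plain logistic
#' regression, fitted by the package's own iteratively reweighted least
#' squares.
#'
#' @param rows Standardised design rows with `response`,
#'   `animal_year_id` and covariate columns.
#' @param spec A [model_spec()] (landscape scale) or character vector of
#'   terms.
#' @param nodes Quadrature nodes (default 15).
#' @param var_fixed Optional fixed value for the random-intercept variance
#'   (only 0 is meaningful: forces the GLM reduction).
#' @param group Grouping column (default `"animal_year_id"`).
#' @param max_iter Optimiser iteration cap.
#' @param se Compute standard errors (numeric observed information) and
#'   Newton-polish the optimum? Skipping this roughly halves the cost of
#'   fits needed only for likelihood comparisons (candidate ranking,
#'   cross-validation).
#' @return An `rsf_fit`: `coefficients` (with intercept), `se`, `vcov`,
#'   `sigma_u` (random-intercept SD), `logLik` (marginal), `k` (parameter
#'   count incl. the variance), `n`, `n_groups`, `converged`, `boundary`,
#'   `nodes`, `terms`, `spec`.
#' @export
fit_rsf_mixed <- function(rows, spec, nodes = 15, var_fixed = NULL,
                          group = "animal_year_id", max_iter = 400,
                          se = TRUE) {
  terms <- if (inherits(spec, "model_spec")) spec_terms(spec) else spec
  stopifnot("response" %in% names(rows))
  X <- build_model_matrix(rows, terms, intercept = TRUE)
  y <- rows$response
  g <- factor(rows[[group]])
  n_groups <- nlevels(g)
  if (qr(X)$rank < ncol(X)) {
    stopf("design is rank deficient after screening (rank < %d)", ncol(X))
  }
  reduce_to_glm <- (!is.null(var_fixed) && var_fixed == 0) || n_groups < 2
  if (reduce_to_glm) {
    fit <- irls_logistic(X, y)
    return(structure(
      list(coefficients = fit$beta, se = fit$se, vcov = fit$vcov,
           sigma_u = 0, logLik = fit$logLik, k = ncol(X), n = nrow(X),
           n_groups = n_groups, converged = fit$converged, boundary = TRUE,
           nodes = nodes, terms = colnames(X),
           spec = if (inherits(spec, "model_spec")) spec else NULL),
      class = "rsf_fit"
    ))
  }

  gi <- as.integer(g)
  gh <- gauss_hermite(nodes)
  p <- ncol(X)
  env <- new.env()
  env$b_mode <- numeric(n_groups)

  # Marginal negative log-likelihood and analytic gradient at
  # par = c(beta, log sigma). Posterior node weights give the Fisher-identity
  # score; quadrature points are warm-started from the previous call's modes.
  agq <- function(par, want_grad = FALSE) {
    beta <- par[seq_len(p)]
    sigma <- exp(par[p + 1])
    eta0 <- drop(X %*% beta)
    b <- env$b_mode
    for (it in 1:40) {
      mu <- stats::plogis(eta0 + b[gi])
      r <- drop(rowsum(y - mu, gi)) - b / sigma^2
      w <- drop(rowsum(mu * (1 - mu), gi)) + 1 / sigma^2
      step <- r / w
      b <- b + step
      if (max(abs(step)) < 1e-10) break
    }
    env$b_mode <- b
    mu <- stats::plogis(eta0 + b[gi])
    w <- drop(rowsum(mu * (1 - mu), gi)) + 1 / sigma^2
    tau <- 1 / sqrt(w)
    Q <- length(gh$nodes)
    H <- matrix(0, n_groups, Q)      # log-integrand at each node
    bk_all <- outer(tau, sqrt(2) * gh$nodes) + b
    for (k in seq_len(Q)) {
      bk <- bk_all[, k]
      etak <- eta0 + bk[gi]
      llg <- drop(rowsum(y * etak - log1pexp(etak), gi))
      H[, k] <- llg - bk^2 / (2 * sigma^2) - log(sigma) - 0.5 * log(2 * pi)
    }
    lw <- log(sqrt(2) * tau) + matrix(log(gh$weights) + gh$nodes^2,
                                      n_groups, Q, byrow = TRUE)
    M <- H + lw
    ll_g <- logsumexp_rows(M)
    nll <- -sum(ll_g)
    if (!want_grad) return(nll)
    post <- exp(M - ll_g)            # posterior node weights per group
    # Fisher identity: the beta-score is X'(y - E_post[mu]), with the
    # posterior mean response accumulated over quadrature nodes.
    mu_post <- numeric(length(y))
    for (k in seq_len(Q)) {
      mu_post <- mu_post + post[gi, k] * stats::plogis(eta0 + bk_all[gi, k])
    }
    grad_beta <- drop(crossprod(X, y - mu_post))
    grad_theta <- sum(post * (bk_all^2 / sigma^2 - 1))
    list(nll = nll, grad = -c(grad_beta, grad_theta))
  }

  start_glm <- irls_logistic(X, y)
  par0 <- c(start_glm$beta, log(0.5))
  fn <- function(par) agq(par)
  gr <- function(par) agq(par, want_grad = TRUE)$grad
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), log(1e-6)),
                      control = list(maxit = max_iter, factr = 1e4))
  if (opt$convergence != 0) {
    # restart once with a fresh quasi-Newton memory
    opt <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                        lower = c(rep(-Inf, p), log(1e-6)),
                        control = list(maxit = max_iter, factr = 1e4))
  }
  par_hat <- opt$par
  ll_hat <- -opt$value
  # a stationary point with a tiny score is converged even if the optimiser
  # stopped on its iteration budget
  converged <- opt$convergence == 0 || max(abs(gr(par_hat))) < 1e-3
  if (se) {
    # Newton-style polish with a numeric Hessian (which also yields the SEs)
    Hn <- stats::optimHess(par_hat, fn, gr)
    step <- tryCatch(solve(Hn, gr(par_hat)), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step)) && fn(par_hat - step) < opt$value) {
      par_hat <- par_hat - step
      ll_hat <- -fn(par_hat)
      Hn <- stats::optimHess(par_hat, fn, gr)
    }
    vcov_all <- tryCatch(solve(Hn), error = function(e) matrix(NA_real_, p + 1, p + 1))
  } else {
    vcov_all <- matrix(NA_real_, p + 1, p + 1)
  }
  beta_hat <- stats::setNames(par_hat[seq_len(p)], colnames(X))
  sigma_hat <- unname(exp(par_hat[p + 1]))
  vc <- vcov_all[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta_hat, se = sqrt(pmax(diag(vc), 0)), vcov = vc,
         sigma_u = sigma_hat, logLik = ll_hat, k = p + 1,
         n = nrow(X), n_groups = n_groups,
         converged = converged, boundary = sigma_hat < 1e-3,
         nodes = nodes, terms = colnames(X),
         spec = if (inherits(spec, "model_spec")) spec else NULL),
    class = "rsf_fit"
  )
}

# Plain logistic regression by IRLS (used for starts and for the
# variance-zero reduction).
irls_logistic <- function(X, y, max_iter = 60, tol = 1e-12) {
  p <- ncol(X)
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    ll <- sum(y * eta - log1pexp(eta))
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, mu * (1 - mu) * X)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = stats::setNames(drop(beta), colnames(X)), se = sqrt(diag(vc)),
       vcov = vc, logLik = sum(y * eta - log1pexp(eta)), converged = converged)
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> n=%d, %d groups, sigma_u=%.3f, logLik=%.3f%s\n",
              x$n, x$n_groups, x$sigma_u, x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(data.frame(beta = x$coefficients, se = x$se))
  invisible(x)
}

#' Relative selection scores
#'
#' Exponential of the fixed linear predictor excluding the intercept and the
#' random effect: a relative (not absolute) selection strength used for
#' ranking, validation and effect plots. Inputs are standardised with the
#' training manifest when one is supplied (`manifest = NULL` means the rows
#' are already on the training scale). An aspect level unseen at fit time is
#' an error.
#'
#' @param fit An `rsf_fit` or `ssf_fit`.
#' @param rows New design rows.
#' @param manifest Optional scaling manifest from [standardize_covariates()].
#' @return Numeric vector of scores (exp of the linear predictor).
#' @export
predict_relative_selection <- function(fit, rows, manifest = NULL) {
  if (!is.null(manifest)) {
    cols <- intersect(manifest$term, names(rows))
    rows <- standardize_covariates(rows, cols = cols, manifest = manifest)$rows
  }
  terms <- setdiff(fit$terms, "(Intercept)")
  # reconstruct original term names from expanded aspect dummies
  has_aspect <- any(grepl("^aspect_", terms))
  plain <- unique(c(if (has_aspect) "aspect", terms[!grepl("^aspect_", terms)]))
  X <- build_model_matrix(rows, plain, intercept = FALSE)
  X <- X[, terms, drop = FALSE]
  beta <- fit$coefficients[terms]
  exp(drop(X %*% beta))
}
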