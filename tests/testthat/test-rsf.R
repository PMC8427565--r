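# Builder for grouped Bernoulli-logit data with a known random-intercept SD.
make_glmm_data <- function(n_groups, n_per, beta, sigma_u, seed = 1) {
  set.seed(seed)
  n <- n_groups * n_per
  g <- sprintf("g%02d", rep(seq_len(n_groups), each = n_per))
  p <- length(beta) - 1
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- beta[1] + drop(X %*% beta[-1]) +
    rep(rnorm(n_groups, 0, sigma_u), each = n_per)
  d <- data.frame(response = rbinom(n, 1, plogis(eta)), animal_year_id = g, X)
  d
}

test_that("null covariates give slope estimates near zero", {
  d <- make_glmm_data(12, 300, beta = c(-1.5, 0, 0), sigma_u = 0.4, seed = 2)
  fit <- fit_rsf_mixed(d, c("x1", "x2"))
  expect_true(fit$converged)
  for (v in c("x1", "x2")) {
    expect_lt(abs(fit$coefficients[v]) / fit$se[v], 3)
  }
})

test_that("variance fixed at zero reduces to plain logistic regression", {
  d <- make_glmm_data(6, 200, beta = c(-1, 0.8, -0.5), sigma_u = 0.3, seed = 3)
  fit0 <- fit_rsf_mixed(d, c("x1", "x2"), var_fixed = 0)
  oracle <- glm(response ~ x1 + x2, binomial, d)
  expect_lt(max(abs(fit0$coefficients - coef(oracle))), 1e-6)
  expect_equal(fit0$logLik, as.numeric(logLik(oracle)), tolerance = 1e-8)
  expect_equal(fit0$sigma_u, 0)
  # a single group triggers the same reduction
  d1 <- d[d$animal_year_id == "g01", ]
  fit1 <- fit_rsf_mixed(d1, c("x1", "x2"))
  oracle1 <- glm(response ~ x1 + x2, binomial, d1)
  expect_lt(max(abs(fit1$coefficients - coef(oracle1))), 1e-6)
})

test_that("quadrature log-likelihood matches dense numerical integration", {
  # tiny problem: 2 groups x 20 rows, evaluated at the fitted parameters
  d <- make_glmm_data(2, 20, beta = c(-0.5, 0.7), sigma_u = 0.6, seed = 4)
  fit <- fit_rsf_mixed(d, "x1", nodes = 25)
  X <- cbind(1, d$x1)
  ll_dense <- oracle_mixed_loglik_dense(fit$coefficients, fit$sigma_u,
                                        X, d$response, d$animal_year_id,
                                        lim = 10, n_grid = 40001)
  expect_equal(fit$logLik, ll_dense, tolerance = 1e-8)
})

test_that("fit matches brute-force maximisation of the dense-integrated likelihood", {
  d <- make_glmm_data(15, 60, beta = c(-0.8, 0.9), sigma_u = 0.7, seed = 5)
  fit <- fit_rsf_mixed(d, "x1", nodes = 25)
  X <- cbind(1, d$x1)
  oracle <- optim(
    c(0, 0, log(0.5)),
    function(par) -oracle_mixed_loglik_dense(par[1:2], exp(par[3]), X,
                                             d$response, d$animal_year_id,
                                             lim = 8, n_grid = 2001),
    method = "BFGS", control = list(reltol = 1e-14, maxit = 500)
  )
  expect_lt(max(abs(fit$coefficients - oracle$par[1:2])), 1e-4)
  expect_lt(abs(fit$sigma_u - exp(oracle$par[3])), 1e-3)
})

test_that("fit agrees with lme4 adaptive quadrature", {
  skip_if_not_installed("lme4")
  d <- make_glmm_data(20, 400, beta = c(-2, 0.8, -0.5, 0.3), sigma_u = 0.5,
                      seed = 6)
  fit <- fit_rsf_mixed(d, c("x1", "x2", "x3"), nodes = 15)
  m <- lme4::glmer(response ~ x1 + x2 + x3 + (1 | animal_year_id),
                   data = d, family = binomial, nAGQ = 15)
  expect_lt(max(abs(fit$coefficients - lme4::fixef(m))), 2e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(as.matrix(stats::vcov(m))))), tolerance = 1e-2)
  expect_equal(fit$sigma_u, sqrt(unlist(lme4::VarCorr(m))[[1]]),
               tolerance = 1e-3)
})

test_that("boundary variance is reported, with the fit still returned", {
  d <- make_glmm_data(10, 150, beta = c(-1, 0.6), sigma_u = 0, seed = 7)
  fit <- fit_rsf_mixed(d, "x1")
  expect_true(fit$converged)
  expect_lt(fit$sigma_u, 0.1)
  expect_true(is.finite(fit$logLik))
})

test_that("relative selection scores behave as exp of the linear predictor", {
  d <- make_glmm_data(8, 120, beta = c(-1, 1.2, -0.6), sigma_u = 0.3, seed = 8)
  fit <- fit_rsf_mixed(d, c("x1", "x2"))
  # all-zero standardised row scores exactly 1 (intercept excluded)
  z0 <- data.frame(x1 = 0, x2 = 0)
  expect_equal(predict_relative_selection(fit, z0), 1)
  # monotone in a positively selected covariate
  zz <- data.frame(x1 = c(-1, 0, 1), x2 = 0)
  sc <- predict_relative_selection(fit, zz)
  expect_true(all(diff(sc) > 0))
  # score ratios equal exp(beta . dx)
  ratio <- sc[3] / sc[1]
  expect_equal(ratio, exp(fit$coefficients[["x1"]] * 2), tolerance = 1e-10)
})

test_that("prediction refuses unseen aspect levels", {
  st <- tiny_landscape(seed = 2, nx = 20, ny = 20)
  used <- data.frame(
    animal_year_id = rep(c("a1", "a2", "a3"), each = 60),
    timestamp = as.POSIXct("2017-06-17 00:00", tz = "UTC") + (1:180) * 7200,
    x = runif(180, 500, 4500), y = runif(180, 500, 4500)
  )
  used <- assign_periods(used)
  mcp <- mcp_available_area(used, ocean = ocean_polygons(st))
  ua <- sample_available_landscape(used, mcp, st, ratio = 5, seed = 2)
  rows <- attribute_covariates(ua, st)
  std <- standardize_covariates(rows)
  fit <- fit_rsf_mixed(std$rows, c("aspect", "elevation", "dn"), nodes = 7)
  bad <- std$rows[1:3, ]
  bad$aspect <- factor(c("north", "east", "ridge"))
  expect_error(predict_relative_selection(fit, bad), "levels")
})
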