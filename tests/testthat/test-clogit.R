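# Small strata builder: k strata, each 1 used + r available, covariates
# supplied as a matrix builder function.
make_strata <- function(n_strata, r, gen, seed = 1, clusters = 2) {
  set.seed(seed)
  rows <- (r + 1) * n_strata
  d <- gen(rows)
  d$stratum_id <- rep(sprintf("s%04d", seq_len(n_strata)), each = r + 1)
  d$response <- rep(c(1, rep(0, r)), n_strata)
  d$animal_year_id <- rep(sprintf("c%02d", rep_len(seq_len(clusters), n_strata)),
                          each = r + 1)
  d
}

test_that("uninformative strata give zero coefficients and the null logLik", {
  # identical covariates within every stratum: beta = 0,
  # logLik = sum log(1/(R+1))
  n_strata <- 40; r <- 5
  d <- make_strata(n_strata, r, function(n) {
    data.frame(x1 = rep(rnorm(n_strata), each = r + 1))
  })
  fit <- fit_ssf_clogit(d, "x1")
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
  expect_equal(fit$logLik, n_strata * log(1 / (r + 1)), tolerance = 1e-10)
})

test_that("estimates match an exhaustive likelihood grid on toy problems", {
  # one binary covariate, 3 strata
  d <- data.frame(
    x1 = c(1, 0, 0, 1, 1, 0, 0, 0, 1),
    stratum_id = rep(c("s1", "s2", "s3"), each = 3),
    response = rep(c(1, 0, 0), 3),
    animal_year_id = "c1"
  )
  fit <- fit_ssf_clogit(d, "x1")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    oracle_clogit_loglik(b, as.matrix(d["x1"]), d$response, d$stratum_id), 0)
  expect_lt(abs(unname(fit$coefficients) - grid[which.max(ll)]), 1e-4)
  expect_equal(fit$logLik, max(ll), tolerance = 1e-6)

  # two continuous covariates against a numeric optimiser on the brute
  # likelihood
  d2 <- make_strata(60, 4, function(n) {
    data.frame(x1 = rnorm(n), x2 = rnorm(n))
  }, seed = 5)
  # impose selection so the optimum is interior
  X2 <- as.matrix(d2[, c("x1", "x2")])
  set.seed(6)
  for (s in unique(d2$stratum_id)) {
    ix <- which(d2$stratum_id == s)
    pr <- exp(X2[ix, ] %*% c(0.8, -0.5))
    pick <- sample(length(ix), 1, prob = pr)
    d2$response[ix] <- 0
    d2$response[ix[pick]] <- 1
  }
  fit2 <- fit_ssf_clogit(d2, c("x1", "x2"))
  oracle <- optim(c(0, 0), function(b)
    -oracle_clogit_loglik(b, X2, d2$response, d2$stratum_id),
    method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(max(abs(fit2$coefficients - oracle$par)), 1e-4)
})

test_that("fit agrees with the survival package on simulated strata", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  st <- tiny_landscape(seed = 7, nx = 40, ny = 40)
  tr <- sim_truth(beta_ssf = c(biomass = 0.4, dn = 0.6, elevation = -0.4),
                  step_kernel = list(shape = 1.6, scale = 400))
  des <- ssf_design_from_sim(tr, st, n_animal_years = 10, fixes_per_animal = 61,
                             seed = 21)
  terms <- c("biomass", "dn", "elevation", "step_length")
  fit <- fit_ssf_clogit(des$rows, terms)
  d <- des$rows
  d$sid <- as.integer(factor(d$stratum_id))
  # one case per stratum: the Breslow partial likelihood IS the conditional
  # logistic likelihood, and it supports clustered robust variances
  sv <- survival::clogit(
    response ~ biomass + dn + elevation + step_length + strata(sid) +
      cluster(animal_year_id),
    data = d, method = "breslow"
  )
  expect_equal(unname(fit$coefficients), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(fit$logLik), unname(sv$loglik[2]), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(sv$naive.var))), tolerance = 1e-4)
  # identical sandwich up to the G/(G-1) small-sample correction, which
  # survival's grouped-jackknife variance does not apply
  G <- fit$n_clusters
  expect_equal(unname(fit$robust_se) / sqrt(G / (G - 1)),
               unname(sqrt(diag(vcov(sv)))), tolerance = 0.01)
})

test_that("duplicating the dataset scales the likelihood as theory predicts", {
  d <- make_strata(80, 5, function(n) data.frame(x1 = rnorm(n), x2 = rnorm(n)),
                   seed = 8, clusters = 8)
  X <- as.matrix(d[, c("x1", "x2")])
  set.seed(9)
  for (s in unique(d$stratum_id)) {
    ix <- which(d$stratum_id == s)
    pr <- exp(X[ix, ] %*% c(0.6, 0))
    pick <- sample(length(ix), 1, prob = pr)
    d$response[ix] <- 0; d$response[ix[pick]] <- 1
  }
  fit1 <- fit_ssf_clogit(d, c("x1", "x2"))
  d2 <- rbind(d, transform(d, stratum_id = paste0(stratum_id, "_dup")))
  fit2 <- fit_ssf_clogit(d2, c("x1", "x2"))
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-6)
  expect_equal(fit2$logLik, 2 * fit1$logLik, tolerance = 1e-6)
  expect_equal(fit2$se, fit1$se / sqrt(2), tolerance = 1e-5)
  # same cluster ids on the duplicate: the QIC trace term doubles
  expect_equal(sum(diag(solve(fit2$info, fit2$meat))),
               2 * sum(diag(solve(fit1$info, fit1$meat))), tolerance = 1e-5)
})

test_that("the conditional likelihood absorbs stratum-constant shifts", {
  d <- make_strata(50, 4, function(n) data.frame(x1 = rnorm(n)), seed = 10)
  set.seed(11)
  for (s in unique(d$stratum_id)) {
    ix <- which(d$stratum_id == s)
    pr <- exp(d$x1[ix] * 0.7)
    pick <- sample(length(ix), 1, prob = pr)
    d$response[ix] <- 0; d$response[ix[pick]] <- 1
  }
  fit <- fit_ssf_clogit(d, "x1")
  d_shift <- d
  d_shift$x1 <- d$x1 + 100   # adding a constant changes no slope
  fit_shift <- fit_ssf_clogit(d_shift, "x1")
  expect_equal(fit$coefficients, fit_shift$coefficients, tolerance = 1e-6)
})

test_that("separation is detected and flagged divergent", {
  # covariate perfectly ranks the used step first in every stratum
  d <- make_strata(30, 3, function(n) data.frame(x1 = numeric(n)), seed = 12)
  d$x1 <- ifelse(d$response == 1, 1, 0)
  fit <- fit_ssf_clogit(d, "x1")
  expect_true(fit$divergent)
})
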