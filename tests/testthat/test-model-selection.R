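test_that("forage candidate enumeration matches the published design", {
  specs <- build_candidate_set("post_calving", "landscape")
  expect_length(specs, 13)   # null + base + 11 forage structures
  labels <- vapply(specs, function(s) s$label, "")
  expect_true("Null" %in% labels)
  expect_true("Base habitat" %in% labels)
  expect_true("Base habitat + BM + BM^2 + DN + DE" %in% labels)
  # biomass^2 never appears without biomass
  for (sp in specs) {
    if (sp$biomass_quad) expect_true("biomass" %in% sp$forage)
  }
  # a flagged biomass-DE pair removes every spec containing both: 9 remain
  fl <- data.frame(var1 = "biomass", var2 = "de", r = -0.83)
  specs_fl <- build_candidate_set("oestrid", "landscape", flagged = fl)
  expect_length(specs_fl, 9)
  # no forage components at all leaves just null + base
  expect_length(build_candidate_set("x", "landscape",
                                    forage_components = character(0)), 2)
  # patch-scale specs carry step length everywhere, incl. the null model
  pspecs <- build_candidate_set("post_calving", "patch")
  for (sp in pspecs) expect_true("step_length" %in% spec_terms(sp))
})

test_that("insect-stage candidates add the index and interaction subsets", {
  top <- model_spec("landscape", "mosquito",
                    forage = c("biomass", "dn", "de"), biomass_quad = TRUE)
  specs <- build_insect_candidate_set(top, "mi")
  expect_length(specs, 9)   # forage model + MI with 8 interaction subsets
  labs <- vapply(specs, function(s) s$label, "")
  expect_true(any(grepl("MI\\*BM\\^2", labs)))   # quadratic rides with biomass
  full <- specs[[length(specs)]]
  expect_setequal(full$insect_interactions, c("biomass", "dn", "de"))
  # interactions require both mains
  expect_error(model_spec("landscape", forage = "dn", insect = "mi",
                          insect_interactions = "de"), "main effects")
  expect_error(model_spec("landscape", forage = "dn",
                          insect_interactions = "dn"), "main effect")
})

test_that("AIC, delta and weights follow their definitions", {
  f <- function(ll, k) list(logLik = ll, k = k, converged = TRUE,
                            spec = list(label = paste0("m", k)))
  expect_equal(aic(f(-100, 5)), 210)
  tab1 <- delta_and_weights(list(f(-100, 5)), "aic")
  expect_equal(tab1$weight, 1)
  tab2 <- delta_and_weights(list(f(-100, 5), f(-101, 4)), "aic")
  expect_equal(tab2$delta[1], 0)
  expect_equal(tab2$weight, c(0.5, 0.5))
  expect_equal(sum(tab2$weight), 1)
})

test_that("QIC reduces to 2k penalty when robust equals naive", {
  d <- data.frame(
    x1 = rnorm(120), x2 = rnorm(120),
    stratum_id = rep(sprintf("s%02d", 1:20), each = 6),
    response = rep(c(1, rep(0, 5)), 20),
    animal_year_id = rep(sprintf("c%02d", 1:10), each = 12)
  )
  fit <- fit_ssf_clogit(d, c("x1", "x2"))
  expect_equal(qic(fit, meat = fit$info), -2 * fit$logLik + 2 * fit$k,
               tolerance = 1e-10)
  # with truly independent single-stratum clusters at the null model the
  # QIC penalty approaches the AIC penalty
  d2 <- d
  d2$animal_year_id <- d2$stratum_id
  fit2 <- fit_ssf_clogit(d2, c("x1", "x2"))
  expect_lt(abs(sum(diag(solve(fit2$info, fit2$meat))) - fit2$k) / fit2$k, 0.35)
})

test_that("QIC penalty concentrates near 2k for independent clusters at scale", {
  # simulation of the trace term: data generated under the model with one
  # stratum per cluster makes robust ~= naive, so penalty/2k -> 1
  set.seed(31)
  n_strata <- 2000
  r <- 5
  d <- data.frame(x1 = rnorm(n_strata * (r + 1)), x2 = rnorm(n_strata * (r + 1)))
  d$stratum_id <- rep(sprintf("s%05d", seq_len(n_strata)), each = r + 1)
  d$animal_year_id <- d$stratum_id
  X <- as.matrix(d[, c("x1", "x2")])
  beta_true <- c(0.5, -0.4)
  d$response <- 0
  pick <- vapply(split(seq_len(nrow(d)), d$stratum_id), function(ix) {
    ix[sample.int(r + 1, 1, prob = exp(X[ix, ] %*% beta_true))]
  }, 0L)
  d$response[pick] <- 1
  fit <- fit_ssf_clogit(d, c("x1", "x2"))
  penalty <- sum(diag(solve(fit$info, fit$meat)))
  expect_lt(abs(penalty - fit$k) / fit$k, 0.1)
})

test_that("adding a useless covariate never lowers -2logLik", {
  set.seed(17)
  st <- tiny_landscape(seed = 13, nx = 30, ny = 30)
  tr <- sim_truth(beta_ssf = c(dn = 0.6), step_kernel = list(shape = 2, scale = 300))
  des <- ssf_design_from_sim(tr, st, n_animal_years = 6, fixes_per_animal = 51,
                             seed = 41)
  f_small <- fit_ssf_clogit(des$rows, c("dn", "step_length"))
  f_big <- fit_ssf_clogit(des$rows, c("dn", "de", "step_length"))
  expect_gte(f_big$logLik, f_small$logLik - 1e-8)
  # and the nesting holds for the mixed RSF too
  d <- data.frame(response = rbinom(600, 1, 0.3),
                  animal_year_id = rep(c("a", "b", "c"), each = 200),
                  x1 = rnorm(600), x2 = rnorm(600))
  r_small <- fit_rsf_mixed(d, "x1", nodes = 7)
  r_big <- fit_rsf_mixed(d, c("x1", "x2"), nodes = 7)
  expect_gte(r_big$logLik, r_small$logLik - 1e-6)
})

test_that("movement candidate ladder has the six published structures", {
  cands <- movement_candidates("mi")
  expect_length(cands, 6)
  expect_true(all(c("MI + MI^2 + OD + OD^2", "OD") %in% names(cands)))
  expect_setequal(cands[["MI + MI^2 + OD + OD^2"]],
                  c("mi", "mi_sq", "od", "od_sq"))
  oc <- movement_candidates("oi")
  expect_true(all(grepl("^OI|^OD", names(oc))))
})
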