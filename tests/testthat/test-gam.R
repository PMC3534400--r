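test_that("intercept-only binomial fit recovers the success probability", {
  set.seed(101)
  n <- 10000
  z <- rbinom(n, 1, 0.75)
  fit <- fit_binomial_gam(data.frame(x = rnorm(n)), z)
  expect_equal(plogis(fit$coef[["(Intercept)"]]), 0.75, tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("binomial fit recovers a linear logit slope", {
  set.seed(102)
  n <- 20000
  x <- runif(n, -1, 1)
  z <- rbinom(n, 1, plogis(0.3 + 2.0 * x))
  fit <- fit_binomial_gam(data.frame(x = x), z, covariates = "x")
  # slope of the fitted smooth over the covariate range
  eta <- submodel_eta(fit, data.frame(x = c(-0.5, 0.5)))
  expect_equal(eta[2] - eta[1], 2.0, tolerance = 0.1)
})

test_that("perfectly balanced intercept-only data gives a zero intercept", {
  z <- rep(c(0L, 1L), 500)
  fit <- fit_binomial_gam(data.frame(x = seq_len(1000)), z)
  expect_equal(fit$coef[["(Intercept)"]], 0, tolerance = 1e-8)
  expect_error(fit_binomial_gam(data.frame(x = 1:10), rep(1L, 10)),
               "binomial component")
})

test_that("zero-truncated weighted Poisson log-likelihood is consistent", {
  # theta = 0: closed-form zero-truncated Poisson log-likelihood
  set.seed(103)
  counts <- rpois(500, 3); counts <- counts[counts > 0]
  lam <- runif(length(counts), 1, 5)
  closed <- sum(dpois(counts, lam, log = TRUE) - log(1 - exp(-lam)))
  expect_equal(ztwp_loglik(counts, lam, 0), closed, tolerance = 1e-8)
  # single-observation composition
  expect_equal(ztwp_loglik(2L, 2, 0.3), log(dztwpois(2, 2, 0.3)))
  # likelihood peaks near the data
  expect_gt(ztwp_loglik(rep(3L, 50), rep(3, 50), 0),
            ztwp_loglik(rep(3L, 50), rep(6, 50), 0))
  expect_error(ztwp_loglik(c(1L, 0L), 2, 0), ">= 1")
})

test_that("intercept-only ZTWP fit recovers the rate", {
  set.seed(104)
  counts <- simulate_from_model(function(x) rep(1, length(x)),
                                function(x) rep(3, length(x)),
                                theta = 0, covariates = numeric(10000),
                                seed = 104)
  fit <- fit_ztwp_gam(data.frame(x = rnorm(10000)), counts, theta = 0)
  expect_equal(exp(fit$coef[["(Intercept)"]]), 3, tolerance = 0.1)
})

test_that("degenerate all-ones counts push the fitted ZT mean to one", {
  counts <- rep(1L, 2000)
  fit <- suppressWarnings(
    fit_ztwp_gam(data.frame(x = rnorm(2000)), counts, theta = 0))
  lam_hat <- exp(max(min(fit$coef[["(Intercept)"]], 5), -10))
  expect_equal(ztp_mean(lam_hat), 1, tolerance = 1e-3)
})

test_that("penalized deviance is non-increasing across IRLS iterations", {
  set.seed(105)
  n <- 3000
  x <- runif(n, -2, 2)
  z <- rbinom(n, 1, plogis(sin(2 * x)))
  fit <- fit_binomial_gam(data.frame(x = x), z, covariates = "x",
                          penalty_grid = 1)
  expect_true(all(diff(fit$dev_trace) <= 1e-10))
  counts <- simulate_from_model(function(x) rep(1, length(x)),
                                function(x) exp(0.8 + 0.4 * sin(x)),
                                theta = 0.3, covariates = x, seed = 5105)
  fitp <- suppressWarnings(
    fit_ztwp_gam(data.frame(x = x), counts, theta = 0.3,
                 covariates = "x", penalty_grid = 1))
  expect_true(all(diff(fitp$dev_trace) <= 1e-10))
})

test_that("infinite smoothing collapses each smooth to a linear GLM fit", {
  set.seed(106)
  n <- 4000
  x <- runif(n)
  z <- rbinom(n, 1, plogis(-0.5 + 1.5 * x))
  fit <- fit_binomial_gam(data.frame(x = x), z, covariates = "x",
                          penalty_grid = 1e7)
  glm_fit <- glm(z ~ x, family = binomial())
  eta_gam <- submodel_eta(fit, data.frame(x = x))
  eta_glm <- unname(predict(glm_fit))
  expect_equal(eta_gam, eta_glm, tolerance = 1e-4)
})

test_that("binomial smooth agrees with an independent GAM engine", {
  skip_if_not_installed("mgcv")
  set.seed(107)
  n <- 8000
  x <- runif(n, -2, 2)
  z <- rbinom(n, 1, plogis(1 + sin(1.5 * x)))
  fit <- fit_binomial_gam(data.frame(x = x), z, covariates = "x")
  ref <- mgcv::gam(z ~ s(x, k = 10), family = binomial())
  grid <- data.frame(x = seq(-1.8, 1.8, length.out = 50))
  eta1 <- submodel_eta(fit, grid)
  eta2 <- unname(predict(ref, grid))
  expect_lt(sqrt(mean((plogis(eta1) - plogis(eta2))^2)), 0.02)
})

test_that("theta profile behaves on degenerate grids and recovers zero", {
  set.seed(108)
  x <- runif(4000, -1, 1)
  counts <- simulate_from_model(function(x) rep(1, length(x)),
                                function(x) exp(1 + 0.5 * x),
                                theta = 0, covariates = x, seed = 8108)
  d <- data.frame(x = x)
  one <- suppressWarnings(
    estimate_theta(d, counts, covariates = "x", grid = 0.3,
                   penalty_grid = 1))
  expect_equal(one$theta, 0.3)
  prof <- suppressWarnings(
    estimate_theta(d, counts, covariates = "x",
                   grid = c(0, 0.2, 0.8), penalty_grid = 1))
  expect_equal(prof$theta, 0)
  expect_equal(which.max(prof$profile$penalized_loglik), 1L)
})

test_that("model refit on identical data is bit-for-bit deterministic", {
  sim <- fixture_flows(n_reads = 30, seed = 9)
  args <- list(sim$flows, penalty_grid = 1, theta_grid = c(0, 0.4))
  m1 <- suppressWarnings(do.call(fit_hurdle_model, args))
  m2 <- suppressWarnings(do.call(fit_hurdle_model, args))
  expect_identical(m1$binomial$coef, m2$binomial$coef)
  expect_identical(m1$poisson$coef, m2$poisson$coef)
  expect_identical(m1$theta, m2$theta)
})

test_that("training refuses unusable inputs with informative errors", {
  sim <- fixture_flows(n_reads = 5, seed = 10)
  flows <- sim$flows
  flows$ref_hpl <- NULL
  expect_error(fit_hurdle_model(flows), "ref_hpl")
  pos_only <- sim$flows[sim$flows$ref_hpl > 0, ]
  expect_error(suppressWarnings(fit_hurdle_model(pos_only)),
               "binomial component")
  few <- sim$flows[1:40, ]
  expect_error(fit_hurdle_model(few, min_positive = 1000), "positive flows")
})
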