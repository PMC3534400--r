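param_grid <- expand.grid(lambda = c(0.2, 1, 2.5, 6, 10),
                          theta = c(0, 0.1, 0.5, 2))

test_that("normalizing constant matches the brute-force series oracle", {
  expect_equal(wpois_norm(1, 0), 1, tolerance = 1e-12)
  for (i in seq_len(nrow(param_grid))) {
    lam <- param_grid$lambda[i]; th <- param_grid$theta[i]
    expect_equal(wpois_norm(lam, th), oracle_wp_norm(lam, th),
                 tolerance = 1e-10, label = sprintf("W(%g, %g)", lam, th))
    expect_true(wpois_norm(lam, th) <= 1 && wpois_norm(lam, th) > 0)
  }
  # dominating weight: only the n = 1 term survives at lambda = 1, large theta
  expect_equal(wpois_norm(1, 100), exp(-1), tolerance = 1e-6)
  expect_equal(wpois_norm(1, 100), oracle_wp_norm(1, 100), tolerance = 1e-12)
})

test_that("weighted Poisson pmf matches the oracle and normalizes", {
  expect_equal(dwpois(0, 1, 0), exp(-1), tolerance = 1e-12)
  expect_equal(dwpois(2, 2.5, 0.3), oracle_wp_pmf(2, 2.5, 0.3),
               tolerance = 1e-10)
  for (i in seq_len(nrow(param_grid))) {
    lam <- param_grid$lambda[i]; th <- param_grid$theta[i]
    n <- 0:40
    expect_equal(dwpois(n, lam, th), oracle_wp_pmf(n, lam, th),
                 tolerance = 1e-10)
    expect_equal(sum(dwpois(0:200, lam, th)), 1, tolerance = 1e-8)
  }
  # weights concentrate mass at n = lambda
  p <- dwpois(0:2, 1, 5)
  expect_true(p[2] > p[1] && p[2] > p[3])
  expect_error(dwpois(-1, 1, 0), "non-negative")
  expect_error(dwpois(1, 1, -0.2), "theta")
  expect_error(dwpois(1, Inf, 0), "lambda")
})

test_that("zero-truncated pmf composes correctly and excludes zero", {
  expect_equal(dztwpois(1, 0.01, 0), 1, tolerance = 1e-2)
  expect_equal(dztwpois(3, 2.5, 0.3), oracle_ztwp_pmf(3, 2.5, 0.3),
               tolerance = 1e-10)
  expect_equal(sum(dztwpois(1:200, 4, 0.2)), 1, tolerance = 1e-9)
  expect_error(dztwpois(0, 2, 0.1), "hurdle")
})

test_that("hurdle pmf mixes the two parts and sums to one on the grid", {
  expect_equal(dhurdle(0, pi = 0, lambda = 2, theta = 0.1), 1)
  expect_equal(dhurdle(0, pi = 0.8, lambda = 2.5, theta = 0.3), 0.2)
  expect_equal(dhurdle(2, pi = 0.8, lambda = 2.5, theta = 0.3),
               0.8 * dztwpois(2, 2.5, 0.3), tolerance = 1e-12)
  for (i in seq_len(nrow(param_grid))) {
    lam <- param_grid$lambda[i]; th <- param_grid$theta[i]
    p <- dhurdle(0:200, pi = 0.7, lambda = lam, theta = th)
    expect_equal(sum(p), 1, tolerance = 1e-8)
    expect_equal(p, oracle_hurdle_pmf(0:200, 0.7, lam, th),
                 tolerance = 1e-10)
  }
  expect_error(dhurdle(1, pi = 1.2, lambda = 1, theta = 0), "pi")
})

test_that("theta = 0 reproduces the (zero-truncated) Poisson exactly", {
  for (lam in c(0.2, 1, 2.5, 6, 10)) {
    n <- 0:30
    expect_equal(dwpois(n, lam, 0), dpois(n, lam), tolerance = 1e-12)
    expect_equal(dztwpois(n[-1], lam, 0),
                 dpois(n[-1], lam) / (1 - dpois(0, lam)),
                 tolerance = 1e-12)
  }
})

test_that("positive theta induces underdispersion of the positive part", {
  for (lam in c(0.2, 1, 2.5, 6, 10)) {
    m0 <- hurdle_moments(pi = 1, lambda = lam, theta = 0)
    for (th in c(0.1, 0.5, 2)) {
      m <- hurdle_moments(pi = 1, lambda = lam, theta = th)
      expect_lt(m$var / m$mean, m0$var / m0$mean)
    }
    m1 <- hurdle_moments(pi = 1, lambda = lam, theta = 0.5)
    expect_lt(m1$var / m1$mean, 1)
  }
})

test_that("hurdle moments match closed forms in the Poisson limit", {
  m <- hurdle_moments(pi = 1, lambda = 3, theta = 0)
  expect_equal(m$mean, ztp_mean(3), tolerance = 1e-10)
  expect_equal(m$var, ztp_var(3), tolerance = 1e-10)
  m0 <- hurdle_moments(pi = 0, lambda = 3, theta = 0)
  expect_equal(m0$mean, 0)
  expect_equal(m0$var, 0)
})
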