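# Independent brute-force oracles used across the test files.
# These deliberately avoid the package's own series code: raw terms are
# computed directly in log space and summed to a fixed n = 200.

oracle_wp_terms <- function(lambda, theta, N = 200L) {
  n <- 0:N
  exp(n * log(lambda) - lambda - lgamma(n + 1) - theta * (lambda - n)^2)
}

oracle_wp_norm <- function(lambda, theta, N = 200L) {
  sum(oracle_wp_terms(lambda, theta, N))
}

oracle_wp_pmf <- function(n, lambda, theta, N = 200L) {
  terms <- oracle_wp_terms(lambda, theta, N)
  terms[n + 1] / sum(terms)
}

oracle_ztwp_pmf <- function(n, lambda, theta, N = 200L) {
  p <- oracle_wp_pmf(n, lambda, theta, N)
  p0 <- oracle_wp_pmf(0L, lambda, theta, N)
  p / (1 - p0)
}

oracle_hurdle_pmf <- function(n, pi, lambda, theta, N = 200L) {
  ifelse(n == 0, 1 - pi, pi * oracle_ztwp_pmf(pmax(n, 1), lambda, theta, N))
}

# closed-form zero-truncated Poisson moments
ztp_mean <- function(lambda) lambda / (1 - exp(-lambda))
ztp_var <- function(lambda) {
  m <- ztp_mean(lambda)
  lambda * (lambda + 1) / (1 - exp(-lambda)) - m^2
}

# textbook Cox-de Boor recursion, independent of splines::splineDesign
deboor_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1L
  B <- matrix(0, length(x), length(knots) - 1L)
  for (i in seq_len(ncol(B)))
    B[, i] <- as.numeric(x >= knots[i] & x < knots[i + 1])
  # make the last basis function right-continuous at the final knot
  B[x == max(knots), max(which(knots < max(knots)))] <- 1
  for (d in seq_len(degree)) {
    Bn <- matrix(0, length(x), ncol(B) - 1L)
    for (i in seq_len(ncol(Bn))) {
      d1 <- knots[i + d] - knots[i]
      d2 <- knots[i + d + 1L] - knots[i + 1L]
      a <- if (d1 > 0) (x - knots[i]) / d1 else 0
      b <- if (d2 > 0) (knots[i + d + 1L] - x) / d2 else 0
      Bn[, i] <- a * B[, i] + b * B[, i + 1L]
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

# small deterministic flow-table fixture built in code
fixture_flows <- function(n_reads = 5, seed = 42) {
  sim <- simulate_flow_data(sim_config(n_reads = n_reads, read_length = 40,
                                       seed = seed))
  sim
}
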