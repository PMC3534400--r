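test_that("reference sequences follow the geometric homopolymer law", {
  cfg1 <- sim_config(n_reads = 20, read_length = 50, hpl_geometric_p = 1,
                     seed = 31)
  for (s in simulate_reference(cfg1)) {
    runs <- rle(strsplit(s, "")[[1]])$lengths
    expect_true(all(runs == 1L))
  }
  cfg2 <- sim_config(n_reads = 200, read_length = 100,
                     hpl_geometric_p = 0.5, seed = 32)
  runs <- unlist(lapply(simulate_reference(cfg2), function(s) {
    r <- rle(strsplit(s, "")[[1]])$lengths
    r[-length(r)]  # drop the truncated final run
  }))
  se <- sqrt(2) / sqrt(length(runs))  # geometric(0.5): mean 2, var 2
  expect_lt(abs(mean(runs) - 2), 3 * se)
})

test_that("simulation is reproducible by seed and independent of order", {
  cfg <- sim_config(n_reads = 6, read_length = 40, seed = 33)
  expect_identical(simulate_reference(cfg), simulate_reference(cfg))
  s1 <- simulate_flow_data(cfg)
  s2 <- simulate_flow_data(cfg)
  expect_identical(s1, s2)
  # per-read substreams: the first 3 reads do not depend on n_reads
  cfg3 <- sim_config(n_reads = 3, read_length = 40, seed = 33)
  s3 <- simulate_flow_data(cfg3)
  expect_identical(s3$truth, s1$truth[1:3])
  expect_identical(s3$flows, s1$flows[s1$flows$read_id %in% names(s3$truth), ])
})

test_that("sequence-to-flow conversion walks the flow order", {
  expect_identical(sequence_to_flows("TTA", "TACG"), c(2L, 1L))
  expect_identical(sequence_to_flows("TTAGG", "TACG"), c(2L, 1L, 0L, 2L))
  expect_identical(sequence_to_flows("AT", "TACG"), c(0L, 1L, 0L, 0L, 1L))
  expect_identical(sequence_to_flows("AT", "TACG", max_flows = 3),
                   c(0L, 1L, 0L))
})

test_that("noiseless limit returns exact signals", {
  cfg <- sim_config(signal_cv = 1e-12, flowgram_noise_sd = 1e-12,
                    background_log2_sd = 1e-9, seed = 34)
  sig <- simulate_signals(c(0L, 1L, 2L, 4L), cfg)
  expect_equal(sig$flowgram, c(0, 1, 2, 4), tolerance = 1e-6)
  expect_equal(sig$raw_intensity[-1],
               cfg$signal_scale * c(1, 2, 4)^cfg$attenuation,
               tolerance = 1e-6)
  expect_equal(sig$raw_intensity[1], 2^cfg$background_log2_mean,
               tolerance = 1e-4)
})

test_that("zero-flow fraction matches the combinatorial expectation", {
  # with run nucleotides uniform among the 3 alternatives, the cyclic
  # flow-order distance between consecutive runs is uniform on {1,2,3}:
  # 2 flows per run on average, half of them zero flows
  cfg <- sim_config(n_reads = 300, read_length = 80, seed = 35)
  sim <- simulate_flow_data(cfg)
  expect_lt(abs(mean(sim$flows$ref_hpl == 0) - 0.5), 0.03)
})

test_that("flowgram noise grows with homopolymer length", {
  cfg <- sim_config(seed = 36)
  hpls <- rep(c(1L, 4L), each = 4000)
  sig <- simulate_signals(hpls, cfg)
  err <- sig$flowgram - hpls
  expect_gt(sd(err[hpls == 4L]), sd(err[hpls == 1L]))
})

test_that("model-based draws match the hurdle law", {
  n <- 100000
  counts <- simulate_from_model(function(x) rep(1, length(x)),
                                function(x) rep(3, length(x)),
                                theta = 0, covariates = numeric(n), seed = 37)
  se <- sqrt(ztp_var(3) / n)
  expect_lt(abs(mean(counts) - ztp_mean(3)), 3 * se)
  expect_true(all(simulate_from_model(function(x) rep(0, length(x)),
                                      function(x) rep(3, length(x)),
                                      0, numeric(1000), seed = 38) == 0L))
  # underdispersion: theta = 2 draws have smaller variance at equal lambda
  c0 <- simulate_from_model(function(x) rep(1, length(x)),
                            function(x) rep(3, length(x)),
                            theta = 0, covariates = numeric(20000), seed = 39)
  c2 <- simulate_from_model(function(x) rep(1, length(x)),
                            function(x) rep(3, length(x)),
                            theta = 2, covariates = numeric(20000), seed = 39)
  expect_lt(var(c2), var(c0))
  # empirical pmf within 3 binomial SEs per cell
  emp <- tabulate(counts, nbins = 12) / n
  p <- dztwpois(1:12, 3, 0)
  se_cell <- sqrt(p * (1 - p) / n)
  keep <- p > 1e-5
  expect_true(all(abs(emp[keep] - p[keep]) <= 3 * se_cell[keep] + 1e-12))
})
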