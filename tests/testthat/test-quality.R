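# the same worked probability vectors as in test-basecall.R
probs_undercall <- c(1e-15, 1e-15, 1e-15, 7.4e-9, 0.83, 0.17, 6.3e-11, 1e-15)
probs_overcall <- c(1e-15, 1.7e-10, 0.29, 0.71, 3e-9, 1e-15)
probs_zero_one <- c(0.75, 0.25, 2.9e-8, 1e-15, 1e-15)

test_that("raw overcall/undercall scores match direct tail computations", {
  # -10 log10 of the printed tails
  expect_equal(qs_overcall(probs_overcall, 3), -10 * log10(1.7e-10 + 0.29 + 1e-15),
               tolerance = 1e-10)
  expect_equal(round(qs_overcall(probs_overcall, 3)), 5)
  expect_equal(qs_overcall(probs_zero_one, 1), -10 * log10(0.75),
               tolerance = 1e-10)
  expect_equal(qs_undercall(probs_undercall, 4),
               -10 * log10(0.17 + 6.3e-11 + 1e-15), tolerance = 1e-10)
  expect_equal(qs_undercall(probs_zero_one, 0),
               -10 * log10(0.25 + 2.9e-8 + 2e-15), tolerance = 1e-10)
  # floor engages when a tail is empty
  expect_equal(qs_overcall(c(1e-18, 1), 1), 150)
  expect_equal(qs_undercall(c(1, 1e-18), 1), 150)
  # k beyond the vector uses the full lower tail: score ~ 0
  expect_equal(qs_overcall(probs_overcall, 50), -10 * log10(sum(probs_overcall)),
               tolerance = 1e-10)
  expect_error(qs_overcall(probs_overcall, 0), ">= 1")
})

test_that("signed scores reproduce all printed worked-example cells", {
  expect_identical(vapply(2:6, function(k) qs_signed(probs_undercall, k),
                          integer(1)),
                   c(0L, 0L, -8L, 1L, 0L))
  expect_identical(vapply(1:5, function(k) qs_signed(probs_overcall, k),
                          integer(1)),
                   c(0L, -1L, 5L, 0L, 0L))
  expect_identical(vapply(0:4, function(k) qs_signed(probs_zero_one, k),
                          integer(1)),
                   c(-6L, 1L, 0L, 0L, 0L))
})

test_that("sign flips with the asymmetry of the two tails", {
  p <- c(0.02, 0.9, 0.08)          # undercall tail heavier at k = 1
  expect_lt(qs_signed(p, 1), 0)
  expect_gt(qs_signed(rev(p), 1), 0)
  # symmetric tails: tie goes to the overcall (positive) side
  expect_gt(qs_signed(c(0.05, 0.9, 0.05), 1), 0)
})

test_that("undercall score is monotone in the mass above k", {
  base <- c(0.2, 0.5, 0.2, 0.1)
  for (extra in c(0.05, 0.1, 0.2)) {
    shifted <- c(0.2 - extra, 0.5, 0.2, 0.1 + extra)
    expect_lte(qs_undercall(shifted, 1), qs_undercall(base, 1))
  }
})

test_that("certain calls hit the cap with a positive sign", {
  p <- c(1e-16, 1e-16, 1)          # all mass at n = 2
  expect_identical(qs_signed(p, 2), 40L)
  expect_equal(qs_overcall(p, 2), 150, tolerance = 1e-6)
})

test_that("per-base Phred scores are capped rounded overcall scores", {
  rd <- assemble_read(4L, "A")
  pm <- matrix(probs_undercall, nrow = 1)
  expect_identical(phred_scores(rd, pm), c(40L, 40L, 40L, 40L))
  # base k = 3 of the overcall example prints as 5
  rd3 <- assemble_read(3L, "A")
  pm3 <- matrix(probs_overcall, nrow = 1)
  expect_identical(phred_scores(rd3, pm3)[3], 5L)
  # certain length-2 homopolymer: both bases at the cap
  rd2 <- assemble_read(2L, "T")
  pm2 <- matrix(c(1e-16, 1e-16, 1), nrow = 1)
  expect_identical(phred_scores(rd2, pm2), c(40L, 40L))
})

test_that("per-position table covers k = 0..called+2 and matches scalars", {
  rd <- assemble_read(c(0L, 3L), c("T", "A"))
  pm <- rbind(probs_zero_one[1:6],
              probs_overcall)
  qt <- position_quality(rd, pm, n_max = 5)
  expect_equal(qt$k[qt$flow_index == 0], 0:2)
  expect_equal(qt$k[qt$flow_index == 1], 0:5)
  row <- qt[qt$flow_index == 1 & qt$k == 3, ]
  expect_equal(row$qs_signed, 5L)
  expect_equal(row$qs_overcall, qs_overcall(probs_overcall, 3))
  expect_true(is.na(qt$qs_overcall[qt$k == 0][1]))
})
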