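test_that("perfect agreement gives ICC 1; a constant rater shift gives less", {
  m <- cbind(c(8, 10, 12, 14), c(8, 10, 12, 14))
  r <- icc_a1(m)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_low, 1)
  shifted <- cbind(c(8, 10, 12, 14), c(13, 15, 17, 19))
  expect_lt(icc_a1(shifted)$icc, 1)
  expect_equal(icc_a1(shifted)$icc, oracle_icc_a1(shifted))
})

test_that("a fixed 6x2 table matches the explicit sums-of-squares oracle", {
  m <- cbind(c(10, 12, 14, 9, 11, 13), c(10, 13, 14, 9, 12, 13))
  r <- icc_a1(m)
  expect_equal(r$icc, oracle_icc_a1(m), tolerance = 1e-12)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  expect_lt(r$p_value, 0.05)
})

test_that("ICC is invariant to a global shift but penalized by a one-rater shift", {
  set.seed(11)
  m <- cbind(sample(5:20, 12, TRUE), sample(5:20, 12, TRUE))
  base <- icc_a1(m)$icc
  expect_equal(icc_a1(m + 7)$icc, base, tolerance = 1e-12)
  m2 <- m
  m2[, 2] <- m2[, 2] + 4
  if (stats::var(rowMeans(m)) > 0) expect_lt(icc_a1(m2)$icc, base)
})

test_that("degenerate tables are rejected", {
  expect_error(icc_a1(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc_a1(cbind(1:5, 2:6, 3:7)), "2 raters")
  expect_error(icc_a1(cbind(c(1, NA), c(1, 2))), "missing")
})

test_that("reliability bands use left-closed Koo-Li cutpoints", {
  expect_equal(icc_band(c(0.96, 0.86, 0.5, 0.49, 0.91, -0.2)),
               c("excellent", "good", "moderate", "poor", "excellent", "poor"))
  # point band vs band supported by the lower confidence bound
  m <- cbind(c(10, 12, 14, 9, 11, 13, 15, 8), c(11, 13, 14, 8, 12, 14, 15, 9))
  r <- icc_a1(m)
  expect_equal(r$band, icc_band(r$icc))
  expect_equal(r$supported_band, icc_band(r$ci_low))
})

test_that("classifier report matches explicit binomial tail sums", {
  truth <- rep(c("average", "below_average"), c(21, 7))
  pred <- truth
  pred[22:28] <- "average"             # 21 of 28 correct
  rep1 <- classifier_report(truth, pred, nir = 0.75)
  expect_equal(rep1$accuracy, 21 / 28)
  expect_equal(rep1$p_vs_nir, oracle_binom_tail(21, 28, 0.75), tolerance = 1e-12)
  expect_equal(rep1$p_vs_nir, 0.5997, tolerance = 1e-3)

  perfect <- classifier_report(rep("a", 20), rep("a", 20), nir = 0.75)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$p_vs_nir, 0.75^20, tolerance = 1e-12)
})

test_that("accuracy equal to the NIR gives h = 0 and power near alpha", {
  truth <- rep(c("a", "b"), c(3, 1))
  pred <- c("a", "a", "a", "a")        # accuracy 0.75
  r <- classifier_report(truth, pred, nir = 0.75)
  expect_equal(r$effect_size_h, 0)
  expect_equal(r$power, 0.05, tolerance = 1e-6)
  expect_true(r$ci_low <= r$accuracy && r$accuracy <= r$ci_high)
})

test_that("classifier input contracts are enforced", {
  expect_error(classifier_report(c("a", "b"), "a", 0.75), "length")
  expect_error(classifier_report("a", "a", 1.2), "proportion")
  expect_error(classifier_report(character(0), character(0), 0.5), "empty")
})

test_that("Clopper-Pearson coverage at n = 28, p = 0.8 is at least nominal", {
  n <- 28; p <- 0.8
  covers <- vapply(0:n, function(x) {
    ci <- stats::binom.test(x, n)$conf.int
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  set.seed(202)
  draws <- stats::rbinom(10000, n, p)
  expect_gte(mean(covers[draws + 1]), 0.95)
})
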