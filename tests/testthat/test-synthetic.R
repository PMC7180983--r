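test_that("noise-free specs yield exactly the constructed peaks, deterministically", {
  spec <- synthetic_spec(n_cycles = 5, period_s = 5, noise_sd_cm = 0,
                         spike_rate_per_s = 0, seed = 12)
  sim <- generate_signal(spec)
  expect_length(sim$signal$samples, 300)
  x <- sim$signal$samples
  above <- rle(x > 30)
  expect_equal(sum(above$values), 5)            # five standing excursions
  expect_equal(max(x), 50)
  expect_equal(min(x), 15)
  expect_equal(sim$truth$total_count, 5L)
  expect_equal(sim$truth$valid_count, 5L)

  again <- generate_signal(spec)
  expect_identical(sim$signal$samples, again$signal$samples)
})

test_that("overlapping-cycle and oversized specs are rejected", {
  expect_error(synthetic_spec(period_s = 1.5, rise_s = 1), "overlapping")
  expect_error(synthetic_spec(n_cycles = 12, period_s = 3), "fit")
})

test_that("older-regime spikes straddle the outlier ceiling", {
  # wide-height bursts (40-150 cm) make an over-ceiling sample near-certain
  hits <- vapply(1:60, function(i) {
    sp <- synthetic_spec(n_cycles = 9, period_s = 3, rise_s = 1,
                         noise_sd_cm = 1, spike_rate_per_s = 0.5,
                         spike_cluster_size = 4,
                         spike_height_cm = c(40, 150), seed = i)
    any(generate_signal(sp)$signal$samples > 99)
  }, logical(1))
  expect_gt(mean(hits), 0.95)
  # the regime batch exercises both preprocessing branches across signals
  batch <- lapply(1:20, function(i) generate_signal(spike_batch_spec(seed = i)))
  over <- vapply(batch, function(s) any(s$signal$samples > 99), logical(1))
  under <- vapply(batch, function(s) {
    any(s$signal$samples > 54 & s$signal$samples <= 99)
  }, logical(1))
  expect_gt(mean(over), 0.5)
  expect_gt(mean(under), 0.9)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- stats::runif(1)
  set.seed(99)
  invisible(generate_signal(synthetic_spec(seed = 5, noise_sd_cm = 1)))
  expect_equal(stats::runif(1), a)
})

test_that("cohorts have the right size, length and regime-specific clustering", {
  young <- generate_cohort(10, "young", seed = 7)
  expect_length(young, 10)
  expect_true(all(vapply(young, function(s) length(s$signal$samples),
                         integer(1)) == 300L))
  older <- generate_cohort(10, "older", seed = 7)
  mean_cluster <- function(cohort) {
    mean(vapply(cohort, function(s) s$spec$spike_cluster_size, numeric(1)))
  }
  expect_gt(mean_cluster(older), mean_cluster(young))
  # determinism subject-by-subject
  again <- generate_cohort(10, "older", seed = 7)
  expect_identical(older[[3]]$signal$samples, again[[3]]$signal$samples)
})

test_that("older cohorts reproduce the scarce, scattered invalid-attempt rate", {
  # target roughly 11 invalid among ~335 transitions (~3%) spread over a
  # handful of subjects
  totals <- invalids <- affected <- numeric(10)
  for (r in 1:10) {
    co <- generate_cohort(30, "older", seed = 300 + r)
    tot <- vapply(co, function(s) s$truth$total_count, integer(1))
    val <- vapply(co, function(s) s$truth$valid_count, integer(1))
    totals[r] <- sum(tot)
    invalids[r] <- sum(tot - val)
    affected[r] <- sum(tot > val)
  }
  rate <- sum(invalids) / sum(totals)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.06)
  expect_true(mean(affected) >= 3 && mean(affected) <= 12)
  expect_gt(mean(totals), 250)
})
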