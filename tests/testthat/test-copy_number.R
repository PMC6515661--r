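test_that("Poisson correction inverts the positive fraction", {
  expect_warning(l0 <- lambda_from_partitions(dpcr_measurement("GFP", 0, 1000)),
                 "no information")
  expect_equal(l0, 0)
  # p = 1 - e^{-1}  =>  lambda = 1
  m <- dpcr_measurement("GFP", round((1 - exp(-1)) * 1e6), 1e6)
  expect_equal(lambda_from_partitions(m), 1, tolerance = 1e-3)
  expect_error(lambda_from_partitions(dpcr_measurement("GFP", 100, 100)),
               "saturated")
})

test_that("simulated partitions recover lambda within propagated error", {
  lam <- 0.5; total <- 20000
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    pos <- rbinom(1, total, 1 - exp(-lam))
    lambda_from_partitions(dpcr_measurement("GFP", pos, total)) - lam
  }, numeric(1))
  p <- 1 - exp(-lam)
  se <- sqrt(p * (1 - p) / total) / (1 - p)  # delta method
  expect_lt(abs(mean(errs)), 3 * se / sqrt(50))
  expect_true(all(abs(errs) < 4 * se))
})

test_that("identical target and reference give a ratio of 1 inside the CI", {
  m <- dpcr_measurement("GFP", 4000, 20000)
  ref <- dpcr_measurement("ALG9", 4000, 20000)
  est <- copies_per_genome(m, ref)
  expect_equal(est$copies_per_genome, 1)
  expect_lte(est$ci_low, 1)
  expect_gte(est$ci_high, 1)
})

test_that("a constructed 3:1 lambda ratio is estimated exactly", {
  lam_ref <- 0.4; total <- 50000
  ref <- dpcr_measurement("ALG9", round((1 - exp(-lam_ref)) * total), total)
  tgt <- dpcr_measurement("mCherry", round((1 - exp(-3 * lam_ref)) * total),
                          total)
  est <- copies_per_genome(tgt, ref)
  expect_equal(est$copies_per_genome, 3, tolerance = 1e-3)
  expect_identical(est$target, "mCherry")
})

test_that("scaling partition totals preserves the estimate, narrows the CI", {
  small <- copies_per_genome(dpcr_measurement("GFP", 600, 2000),
                             dpcr_measurement("ALG9", 300, 2000))
  big <- copies_per_genome(dpcr_measurement("GFP", 6000, 20000),
                           dpcr_measurement("ALG9", 3000, 20000))
  expect_equal(big$copies_per_genome, small$copies_per_genome)
  expect_lt(big$ci_high - big$ci_low, small$ci_high - small$ci_low)
})

test_that("reference degeneracies are estimation errors", {
  tgt <- dpcr_measurement("GFP", 10, 100)
  expect_error(copies_per_genome(tgt, dpcr_measurement("ALG9", 100, 100)),
               "saturated or empty")
  expect_error(copies_per_genome(tgt, dpcr_measurement("ALG9", 0, 100)),
               "saturated or empty")
})

test_that("CI coverage is near nominal at moderate lambda", {
  hits <- 0
  n_sim <- 300
  for (s in 1:n_sim) {
    sim <- generate_dpcr_partitions(true_copies = 2, lambda_ref = 0.5,
                                    total_partitions = 20000, seed = 4000 + s)
    est <- copies_per_genome(sim$target, sim$reference)
    if (est$ci_low <= 2 && 2 <= est$ci_high) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.90)
})

test_that("batch estimation handles per-clone references", {
  counts <- data.frame(
    clone_id = rep(c("c1", "c2"), each = 3),
    target = rep(c("GFP", "mCherry", "ALG9"), 2),
    positive_partitions = c(6000, 3000, 3000, 9000, 3000, 3000),
    total_partitions = 20000
  )
  res <- estimate_copy_numbers(counts)
  expect_equal(nrow(res), 4L)
  expect_gt(res$copies_per_genome[res$clone_id == "c1" &
                                    res$target == "GFP"], 1)
  expect_error(estimate_copy_numbers(counts[counts$target != "ALG9", ]),
               "ALG9")
})
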