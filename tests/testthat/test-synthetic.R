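test_that("a zero-spread population collapses to its center", {
  spec <- clone_spec("c1", list(population_spec(3, 2, spread = 0, weight = 1)),
                     n_events = 50, seed = 1)
  p <- generate_clone_profile(spec)
  expect_equal(p$gfp, rep(10^3, 50))
  expect_equal(p$mcherry, rep(10^2, 50))
})

test_that("population weights are respected (binomial check)", {
  spec <- clone_spec("c1",
                     list(population_spec(2, 2, weight = 0.5),
                          population_spec(4, 4, weight = 0.5)),
                     n_events = 10000, seed = 3)
  p <- generate_clone_profile(spec)
  # populations are far apart; split events at 10^3
  n_low <- sum(p$gfp < 10^3)
  expect_lt(abs(n_low - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("clone generation is seed-deterministic", {
  spec <- clone_spec("c1", list(population_spec(3, 3)), n_events = 100,
                     seed = 7)
  p1 <- generate_clone_profile(spec)
  p2 <- generate_clone_profile(spec)
  expect_identical(p1$gfp, p2$gfp)
  expect_identical(p1$mcherry, p2$mcherry)
})

test_that("archetype datasets have the requested shape and labels", {
  ds <- generate_archetype_dataset(k_archetypes = 16, clones_per_archetype = 3,
                                   n_events = 50, seed = 1)
  expect_length(ds$profiles, 48L)
  expect_equal(ds$labels, rep(1:16, each = 3))
  expect_equal(nrow(ds$manifest), 48L)
  expect_equal(anyDuplicated(ds$manifest$clone_id), 0L)
})

test_that("more jitter lowers the silhouette at the true cluster number", {
  tight <- generate_archetype_dataset(4, 5, n_events = 400, jitter = 0.01,
                                      seed = 11)
  loose <- generate_archetype_dataset(4, 5, n_events = 400, jitter = 0.4,
                                      seed = 11)
  sil <- function(ds) {
    tab <- silhouette_scan(ds$profiles, n_values = 10, k_range = 4)
    tab$mean_silhouette[1]
  }
  expect_gt(sil(tight), sil(loose))
})

test_that("four-population clones show four density peaks at display binning", {
  pops <- lapply(quadrant_centers(), function(ctr) {
    population_spec(ctr[1], ctr[2], spread = 0.15, weight = 0.25)
  })
  p <- generate_clone_profile(clone_spec("c1", pops, n_events = 50000,
                                         seed = 21))
  b <- bin_profile(p, n = 100,
                   ranges = list(gfp = c(1, 5), mcherry = c(1, 5)))
  expect_equal(count_density_peaks(b, smooth_radius = 2, min_height = 0.05),
               4L)
  # dropping a population to negligible weight removes its peak
  pops2 <- pops
  pops2[[4]]$weight <- 0.002
  p2 <- generate_clone_profile(clone_spec("c2", pops2, n_events = 50000,
                                          seed = 22))
  b2 <- bin_profile(p2, n = 100,
                    ranges = list(gfp = c(1, 5), mcherry = c(1, 5)))
  expect_equal(count_density_peaks(b2, smooth_radius = 2, min_height = 0.05),
               3L)
})

test_that("dPCR partition generator matches its design", {
  sim <- generate_dpcr_partitions(1, lambda_ref = 0.5, total_partitions = 1e5,
                                  seed = 5)
  # equal copies: positive fractions agree in expectation
  f_t <- sim$target$positive_partitions / sim$target$total_partitions
  f_r <- sim$reference$positive_partitions / sim$reference$total_partitions
  se <- sqrt(0.4 * 0.6 / 1e5)
  expect_lt(abs(f_t - f_r), 4 * sqrt(2) * se)
  z <- generate_dpcr_partitions(2, lambda_ref = 0, total_partitions = 100,
                                seed = 6)
  expect_equal(z$target$positive_partitions, 0L)
  expect_equal(z$reference$positive_partitions, 0L)
})
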