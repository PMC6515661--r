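test_that("outlier trimming keeps events inside both channels' bounds", {
  set.seed(1)
  p <- tiny_profile(c(rnorm(999, 1000, 50), 1e6), rnorm(1000, 1000, 50))
  expect_identical(trim_outliers(p, 0, 100), p)      # no-op bounds
  tr <- trim_outliers(p, 0.5, 99.5)
  # rank oracle: events outside the 0.5/99.5 percentile on either channel go
  keep <- rep(TRUE, 1000)
  for (ch in c("gfp", "mcherry")) {
    q <- quantile(p[[ch]], c(0.005, 0.995), names = FALSE)
    keep <- keep & p[[ch]] >= q[1] & p[[ch]] <= q[2]
  }
  expect_equal(nrow(tr), sum(keep))
  expect_false(1e6 %in% tr$gfp)
  expect_error(trim_outliers(tiny_profile(5, 5), 25, 75), "degenerate")
  expect_error(trim_outliers(p, 50, 50))
})

test_that("binning follows the half-open rule with clamped edges", {
  rng <- list(gfp = c(0, 10), mcherry = c(0, 10))
  # 5 identical events land in one cell
  b <- bin_profile(tiny_profile(rep(10^3.3, 5), rep(10^7.7, 5)), n = 10,
                   ranges = rng, normalize = FALSE)
  expect_equal(sum(b$grid == 5), 1)
  expect_equal(sum(b$grid), 5)
  bn <- bin_profile(tiny_profile(rep(10^3.3, 5), rep(10^7.7, 5)), n = 10,
                    ranges = rng, normalize = TRUE)
  expect_equal(max(bn$grid), 1)
  # an event exactly on an interior edge goes to the higher bin
  b2 <- bin_profile(tiny_profile(10^2, 10^2), n = 10, ranges = rng,
                    normalize = FALSE)
  expect_equal(b2$grid[3, 3], 1)  # log10 = 2 -> bin [2,3) is the 3rd bin
  # out-of-range events clamp into edge bins; top edge closes the last bin
  b3 <- bin_profile(tiny_profile(c(1e-12 + 1e-300, 10^10, 10^12),
                                 c(10^5, 10^10, 10^11)),
                    n = 10, ranges = rng, normalize = FALSE)
  expect_equal(b3$grid[1, 6] + b3$grid[10, 10], 3)
  expect_error(bin_profile(tiny_profile(c(-1, 2), c(1, 1)), n = 10,
                           ranges = rng), "1 non-positive")
})

test_that("uniform events fill the grid uniformly (multinomial check)", {
  set.seed(99)
  n_ev <- 1e5
  p <- tiny_profile(runif(n_ev, 1, 999), runif(n_ev, 1, 999))
  b <- bin_profile(p, n = 10, ranges = list(gfp = c(1, 999),
                                            mcherry = c(1, 999)),
                   log_transform = FALSE, normalize = FALSE)
  expected <- n_ev / 100
  sd_bin <- sqrt(n_ev * (1 / 100) * (99 / 100))
  expect_true(all(abs(b$grid - expected) < 5 * sd_bin))
})

test_that("Manhattan distance is a metric with the right special values", {
  rng <- list(gfp = c(0, 4), mcherry = c(0, 4))
  b1 <- bin_profile(tiny_profile(10^0.5, 10^0.5), 2, rng, normalize = TRUE)
  b2 <- bin_profile(tiny_profile(10^3.5, 10^3.5), 2, rng, normalize = TRUE)
  expect_equal(manhattan_distance(b1, b1), 0)
  expect_equal(manhattan_distance(b1, b2), 2)  # disjoint support, normalized
  # hand-computed unnormalized 2x2 case
  u1 <- bin_profile(tiny_profile(10^0.5, 10^0.5), 2, rng, normalize = FALSE)
  u2 <- bin_profile(tiny_profile(10^3.5, 10^3.5), 2, rng, normalize = FALSE)
  expect_equal(manhattan_distance(u1, u2), 2)
  # incompatible grids are refused
  b3 <- bin_profile(tiny_profile(1, 1), 3, rng)
  expect_error(manhattan_distance(b1, b3), "incompatible")
  # symmetry + triangle inequality on random triples
  set.seed(7)
  for (rep in 1:20) {
    bs <- lapply(1:3, function(i) {
      bin_profile(tiny_profile(10^runif(50, 0, 4), 10^runif(50, 0, 4)),
                  4, rng, normalize = TRUE)
    })
    d12 <- manhattan_distance(bs[[1]], bs[[2]])
    d21 <- manhattan_distance(bs[[2]], bs[[1]])
    d13 <- manhattan_distance(bs[[1]], bs[[3]])
    d23 <- manhattan_distance(bs[[2]], bs[[3]])
    expect_equal(d12, d21)
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("PAM solves small instances exactly and respects tie rules", {
  # k = N: every point its own medoid, zero cost
  d <- random_distance_matrix(5)
  r <- pam_cluster(d, 5)
  expect_equal(r$medoid_indices, 1:5)
  expect_equal(r$total_cost, 0)
  # two well-separated triplets: PAM matches the exhaustive optimum
  pts <- rbind(matrix(rnorm(6, 0, 0.05), 3), matrix(rnorm(6, 10, 0.05), 3))
  dd <- as.matrix(dist(pts, method = "manhattan"))
  r2 <- pam_cluster(dd, 2)
  expect_equal(r2$total_cost, exhaustive_pam_cost(dd, 2), tolerance = 1e-12)
  expect_equal(sort(unique(r2$assignments)), 1:2)
  expect_true(all(table(r2$assignments) == 3))
  # duplicating every point doubles the cost and keeps the same medoid points
  ddup <- as.matrix(dist(rbind(pts, pts), method = "manhattan"))
  r3 <- pam_cluster(ddup, 2)
  expect_equal(r3$total_cost, 2 * r2$total_cost, tolerance = 1e-12)
  orig_points <- ((r3$medoid_indices - 1) %% 6) + 1
  expect_true(all(orig_points %in% r2$medoid_indices))
})

test_that("PAM never beats the exhaustive bound and usually attains it", {
  set.seed(42)
  hits <- 0
  for (i in 1:100) {
    N <- sample(6:10, 1)
    k <- sample(2:3, 1)
    d <- random_distance_matrix(N)
    cost <- pam_cluster(d, k)$total_cost
    best <- exhaustive_pam_cost(d, k)
    expect_gte(cost, best - 1e-12)
    if (cost <= best + 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("silhouettes match the reference implementation", {
  set.seed(11)
  d <- random_distance_matrix(12)
  r <- pam_cluster(d, 3)
  ref <- cluster::silhouette(r$assignments, dmatrix = d)
  expect_equal(silhouette_widths(d, r$assignments), as.numeric(ref[, 3]),
               tolerance = 1e-12)
})

test_that("silhouette scan picks the true cluster number of separated groups", {
  set.seed(3)
  ds <- generate_archetype_dataset(k_archetypes = 2, clones_per_archetype = 6,
                                   n_events = 500, jitter = 0.02, seed = 5)
  tab <- silhouette_scan(ds$profiles, n_values = 10, k_range = 2:4)
  s2 <- tab$mean_silhouette[tab$k == 2]
  s3 <- tab$mean_silhouette[tab$k == 3]
  expect_gt(s2, s3)
  expect_equal(attr(tab, "recommended")$k, 2L)
  # identical profiles: degenerate flag
  same <- replicate(5, {
    p <- tiny_profile(c(10, 100, 1000), c(10, 100, 1000))
  }, simplify = FALSE)
  expect_warning(tab2 <- silhouette_scan(same, n_values = 5, k_range = 2:3),
                 "identical")
  expect_true(attr(tab2, "degenerate"))
  # k = N - 1 on distinct points forces a singleton scored 0
  d <- random_distance_matrix(6)
  r <- pam_cluster(d, 5)
  widths <- silhouette_widths(d, r$assignments)
  expect_true(any(table(r$assignments) == 1))
  expect_true(any(widths == 0))
})

test_that("archetype masks average member profiles and stay normalized", {
  rng <- list(gfp = c(0, 4), mcherry = c(0, 4))
  b1 <- bin_profile(tiny_profile(c(10, 10), c(10, 1000)), 4, rng)
  b2 <- bin_profile(tiny_profile(c(1000, 10), c(10, 10)), 4, rng)
  b3 <- bin_profile(tiny_profile(c(10, 10), c(10, 1000)), 4, rng)
  d <- profile_distance_matrix(list(b1, b2, b3))
  r <- pam_cluster(d, 2)
  masks <- build_masks(r, list(b1, b2, b3))
  for (m in masks) expect_equal(sum(m$grid), 1, tolerance = 1e-12)
  # the singleton cluster's mask equals its only member
  sizes <- table(r$assignments)
  single <- as.integer(names(sizes)[sizes == 1])
  member <- which(r$assignments == single)
  expect_equal(masks[[single]]$grid, list(b1, b2, b3)[[member]]$grid)
  # cluster of identical profiles: mask equals the profile (idempotence)
  pair <- as.integer(names(sizes)[sizes == 2])
  expect_equal(masks[[pair]]$grid, b1$grid)
})

test_that("presence/absence patterns count as powers of two", {
  expect_equal(enumerate_presence_patterns(4), 16)
  expect_equal(enumerate_presence_patterns(0), 1)
  expect_equal(enumerate_presence_patterns(3), 8)
  expect_error(enumerate_presence_patterns(-1))
})

test_that("the pipeline recovers synthetic archetype labels", {
  ds <- generate_archetype_dataset(k_archetypes = 4, clones_per_archetype = 5,
                                   n_events = 1000, jitter = 0.05, seed = 2)
  out <- cluster_profiles(ds$profiles, n = 10, k = 4)
  ari <- mclust::adjustedRandIndex(out$result$assignments, ds$labels)
  expect_gte(ari, 0.9)
  expect_equal(nrow(out$assignments), 20L)
  expect_length(out$masks, 4L)
})

test_that("profiles round-trip through delimited text and manifests", {
  ds <- generate_archetype_dataset(k_archetypes = 2, clones_per_archetype = 2,
                                   n_events = 100, seed = 9)
  dir <- withr::local_tempdir()
  mf <- write_profiles(ds$profiles, dir)
  back <- load_profiles(mf)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$gfp, ds$profiles[[i]]$gfp)
    expect_equal(back[[i]]$mcherry, ds$profiles[[i]]$mcherry)
    expect_identical(attr(back[[i]], "clone_id"),
                     attr(ds$profiles[[i]], "clone_id"))
  }
})
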