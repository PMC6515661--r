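test_that("an absorbing initial state yields a single-state trajectory", {
  net <- build_network(constitutive_params(alpha = 0))
  tr <- simulate_circuit(net, t_end = 5, seed = 1)
  expect_equal(tr$n_events, 0)
  expect_equal(tr$times, 0)
  expect_equal(tr$final, initial_state(net) + 0.0)
  expect_equal(tr$t_end, 5)
})

test_that("the same seed reproduces a bit-identical trajectory", {
  net <- build_network(default_parameters("strong"))
  t1 <- simulate_circuit(net, t_end = 4, seed = 42)
  t2 <- simulate_circuit(net, t_end = 4, seed = 42)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_circuit(net, t_end = 4, seed = 43)
  expect_false(identical(t1$times, t3$times))
})

test_that("constitutive birth-death mRNA matches the analytic stationary mean", {
  # stationary law of a birth-death process: Poisson(alpha / delta_m)
  alpha <- 10; delta_m <- 1
  net <- build_network(constitutive_params(alpha = alpha, delta_m = delta_m))
  ep <- endpoint_ensemble(net, t_end = 12, n_runs = 200, base_seed = 100)
  target <- alpha / delta_m
  se <- sqrt(target / 200)  # Poisson variance / n
  expect_lt(abs(mean(ep[, "mrnaA"]) - target), 3 * se)
  expect_lt(abs(mean(ep[, "mrnaB"]) - target), 3 * se)
})

test_that("constitutive cascade protein matches the closed-form mean", {
  # linear cascade: E[P] = alpha * beta / (delta_m * delta_p)
  p <- constitutive_params(alpha = 5, delta_m = 2, beta = 2, delta_p = 1)
  net <- build_network(p)
  ep <- endpoint_ensemble(net, t_end = 12, n_runs = 200, base_seed = 7)
  target <- 5 * 2 / (2 * 1)
  # Var[P] = mean * (1 + beta / (delta_m + delta_p)) for the linear cascade
  se <- sqrt(target * (1 + 2 / 3) / 200)
  expect_lt(abs(mean(ep[, "protA"]) - target), 3 * se)
})

test_that("endpoint distribution of a birth-death species is Poisson", {
  alpha <- 5; delta_m <- 1
  net <- build_network(constitutive_params(alpha = alpha, delta_m = delta_m))
  ep <- endpoint_ensemble(net, t_end = 12, n_runs = 2000, base_seed = 1000)
  x <- ep[, "mrnaA"]
  lambda <- alpha / delta_m
  # chi-square GOF against Poisson(lambda), pooling tails to expected >= 5
  kmax <- max(x)
  probs <- dpois(0:kmax, lambda)
  probs[kmax + 1] <- probs[kmax + 1] + ppois(kmax, lambda, lower.tail = FALSE)
  obs <- tabulate(x + 1L, nbins = kmax + 1L)
  expd <- 2000 * probs
  # pool consecutive bins until each pooled bin has expected count >= 5
  o <- numeric(0); e <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(expd)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= 5) { o <- c(o, co); e <- c(e, ce); co <- 0; ce <- 0 }
  }
  if (ce > 0) { o[length(o)] <- o[length(o)] + co
                e[length(e)] <- e[length(e)] + ce }
  stat <- sum((o - e)^2 / e)
  pval <- pchisq(stat, df = length(o) - 1L, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("promoter counts are conserved at every event of every trajectory", {
  for (copies in list(c(1L, 1L), c(3L, 2L))) {
    net <- build_network(default_parameters("strong", copies_A = copies[1],
                                            copies_B = copies[2]))
    for (seed in 1:3) {
      tr <- simulate_circuit(net, t_end = 8, seed = seed)
      sumA <- rowSums(tr$states[, c("proA_free", "proA_act", "proA_rep")])
      sumB <- rowSums(tr$states[, c("proB_free", "proB_act", "proB_rep")])
      expect_true(all(sumA == copies[1]))
      expect_true(all(sumB == copies[2]))
      expect_true(all(tr$states >= 0))
      expect_true(all(diff(tr$times) > 0))
    }
  }
})

test_that("endpoint_ensemble with n_runs = 1 equals the single simulation", {
  net <- build_network(default_parameters("strong"))
  ep <- endpoint_ensemble(net, t_end = 3, n_runs = 1, base_seed = 5)
  tr <- simulate_circuit(net, t_end = 3, seed = 5, record = FALSE)
  expect_equal(ep[1, ], tr$final)
})

test_that("trajectories export to data frame and CSV", {
  net <- build_network(default_parameters("strong"))
  tr <- simulate_circuit(net, t_end = 1, seed = 2)
  df <- as.data.frame(tr)
  expect_identical(names(df), c("time", net$species))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$time, df$time)
})
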