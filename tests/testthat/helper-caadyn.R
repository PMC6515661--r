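# shared test helpers: independent brute-force oracles

# exhaustive k-medoid cost: minimum over all C(N, k) medoid subsets
exhaustive_pam_cost <- function(d, k) {
  d <- as.matrix(d)
  combos <- utils::combn(nrow(d), k)
  min(apply(combos, 2L, function(med) {
    sum(apply(d[, med, drop = FALSE], 1L, min))
  }))
}

# occupancy distribution by explicit enumeration of the 3^m site configurations
enumerate_occupancy <- function(m, act_conc, rep_conc, K_act, K_rep) {
  w <- c(U = 1, A = unname(act_conc / K_act), R = unname(rep_conc / K_rep))
  p <- w / sum(w)
  prob <- matrix(0, m + 1L, m + 1L)
  if (m == 0L) {
    prob[1L, 1L] <- 1
    return(prob)
  }
  configs <- expand.grid(rep(list(c("U", "A", "R")), m),
                         stringsAsFactors = FALSE)
  for (r in seq_len(nrow(configs))) {
    cfg <- as.character(configs[r, ])
    na <- sum(cfg == "A"); nr <- sum(cfg == "R")
    prob[na + 1L, nr + 1L] <- prob[na + 1L, nr + 1L] + prod(p[cfg])
  }
  prob
}

# birth-death parameter set: constitutive transcription only (no feedback)
constitutive_params <- function(alpha = 10, delta_m = 1, beta = 0,
                                delta_p = 1) {
  circuit_parameters(k_act_on = 0, k_rep_on = 0,
                     alpha_active = alpha, alpha_basal = alpha,
                     alpha_repressed = 0, beta = beta,
                     delta_m = delta_m, delta_p = delta_p,
                     repression_mode = "strong")
}

# random 2D point clouds with Manhattan distances, for PAM oracle checks
random_distance_matrix <- function(N) {
  pts <- matrix(stats::runif(2L * N), ncol = 2L)
  as.matrix(stats::dist(pts, method = "manhattan"))
}

# a tiny profile helper
tiny_profile <- function(gfp, mcherry, id = "c1") {
  response_profile(id, gfp, mcherry)
}
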