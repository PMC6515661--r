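# Quasi-steady-state promoter occupancy: competitive dimer binding gives
# statistical weights 1 : (k_act_on/k_act_off) P_self^2 : (k_rep_on/k_rep_off) P_opp^2
mean_transcription_rate <- function(params) {
  if (params$k_act_off <= 0 || params$k_rep_off <= 0) {
    stop("unbinding rates must be > 0 for the quasi-steady-state reduction",
         call. = FALSE)
  }
  Ka <- params$k_act_on / params$k_act_off
  Kr <- params$k_rep_on / params$k_rep_off
  function(P_self, P_opp) {
    wa <- Ka * P_self^2
    wr <- Kr * P_opp^2
    (params$alpha_basal + params$alpha_active * wa +
       params$alpha_repressed * wr) / (1 + wa + wr)
  }
}

#' Mean-field rate field of the CAA circuit
#'
#' Deterministic (mean-field) reduction of the reaction network: promoter
#' occupancies are eliminated by quasi-steady-state, leaving a smooth vector
#' field on `(mRNA_A, P_A, mRNA_B, P_B)`. Per side the occupancy fractions of
#' the free, activator-bound and repressor-bound promoter are proportional to
#' `1 : (k_act_on/k_act_off) P_self^2 : (k_rep_on/k_rep_off) P_opp^2`
#' (competitive dimer binding), and transcription is the occupancy-weighted
#' mix of the three `alpha` rates times the copy number.
#'
#' @param params A [circuit_parameters()] object.
#' @return A function mapping a numeric 4-vector `(mRNA_A, P_A, mRNA_B, P_B)`
#'   to its time derivative.
#' @examples
#' f <- mean_field_rates(default_parameters("strong"))
#' f(c(0, 0, 0, 0))   # basal transcription pushes mRNA up
#' @export
mean_field_rates <- function(params) {
  validate_parameters(params)
  alpha <- mean_transcription_rate(params)
  function(x) {
    mA <- x[1]; PA <- x[2]; mB <- x[3]; PB <- x[4]
    c(params$copies_A * alpha(PA, PB) - params$delta_m * mA,
      params$beta * mA - params$delta_p * PA,
      params$copies_B * alpha(PB, PA) - params$delta_m * mB,
      params$beta * mB - params$delta_p * PB)
  }
}

#' Find mean-field fixed points
#'
#' Multi-start damped Newton search for roots of [mean_field_rates()]. Starts
#' are log-spaced over protein space (plus seeded log-uniform extras), the
#' search runs on the 2D protein reduction (mRNA is slaved to transcription),
#' duplicates are merged at 1e-6 relative tolerance, and each root is
#' classified by the eigenvalues of a numerical Jacobian of the full 4D field
#' (stable iff max real part < -1e-9). Results are sorted by `prot_A`.
#'
#' @param params A [circuit_parameters()] object.
#' @param n_starts Number of starting points (>= 20).
#' @param seed Seed for the extra random starts.
#' @return `data.frame` of class `caa_fixed_points` with columns `mrna_A`,
#'   `prot_A`, `mrna_B`, `prot_B`, `stable`, `leading_eigenvalue`. Empty (with
#'   a warning) if no start converged.
#' @examples
#' find_fixed_points(default_parameters("strong"))
#' @export
find_fixed_points <- function(params, n_starts = 50L, seed = 1L) {
  validate_parameters(params)
  stopifnot(n_starts >= 20L)
  alpha <- mean_transcription_rate(params)
  C <- params$beta / (params$delta_m * params$delta_p)
  nA <- params$copies_A; nB <- params$copies_B
  # protein reduction: P_i = C * n_i * alpha(P_i, P_j)
  resid2 <- function(lp) {
    P <- 10^lp
    c(P[1] - nA * C * alpha(P[1], P[2]),
      P[2] - nB * C * alpha(P[2], P[1]))
  }

  g <- ceiling(sqrt(n_starts))
  grid <- as.matrix(expand.grid(seq(-2, 4, length.out = g),
                                seq(-2, 4, length.out = g)))
  set.seed(as.integer(seed))
  extra <- matrix(stats::runif(2L * n_starts, -2, 4), ncol = 2L)
  starts <- rbind(grid, extra)

  roots <- list()
  for (s in seq_len(nrow(starts))) {
    lp <- starts[s, ]
    for (it in 1:200) {
      r <- resid2(lp)
      if (!all(is.finite(r))) break
      J <- matrix(0, 2, 2)
      h <- 1e-7
      for (j in 1:2) {
        lp2 <- lp; lp2[j] <- lp2[j] + h
        J[, j] <- (resid2(lp2) - r) / h
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) break
      step <- pmin(pmax(step, -1), 1)        # damping in log10 space
      lp <- lp - step
      if (max(abs(resid2(lp))) < 1e-11 * max(1, max(10^lp))) break
    }
    if (all(is.finite(lp)) && max(abs(resid2(lp))) < 1e-9 * max(1, max(10^lp))) {
      roots[[length(roots) + 1L]] <- 10^lp
    }
  }
  if (!length(roots)) {
    warning("no fixed point converged from any start")
    out <- data.frame(mrna_A = numeric(0), prot_A = numeric(0),
                      mrna_B = numeric(0), prot_B = numeric(0),
                      stable = logical(0), leading_eigenvalue = numeric(0))
    class(out) <- c("caa_fixed_points", "data.frame")
    return(out)
  }

  P <- do.call(rbind, roots)
  keep <- rep(TRUE, nrow(P))
  for (i in seq_len(nrow(P))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(P))) {
      if (j > i && keep[j] &&
          all(abs(P[i, ] - P[j, ]) <= 1e-6 * pmax(abs(P[i, ]), 1e-6))) {
        keep[j] <- FALSE
      }
    }
  }
  P <- P[keep, , drop = FALSE]

  field <- mean_field_rates(params)
  rows <- lapply(seq_len(nrow(P)), function(i) {
    PA <- P[i, 1]; PB <- P[i, 2]
    x <- c(nA * alpha(PA, PB) / params$delta_m, PA,
           nB * alpha(PB, PA) / params$delta_m, PB)
    J <- numeric_jacobian(field, x)
    lead <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(mrna_A = x[1], prot_A = x[2], mrna_B = x[3], prot_B = x[4],
               stable = lead < -1e-9, leading_eigenvalue = lead)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$prot_A), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("caa_fixed_points", "data.frame")
  out
}

numeric_jacobian <- function(f, x) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Number of stable mean-field fixed points
#'
#' Convenience wrapper around [find_fixed_points()]: 3 for the strong
#' defaults (tristable: two exclusive states plus a stable symmetric
#' co-expression state), 1 for the weak defaults (monostable).
#'
#' @inheritParams find_fixed_points
#' @return Integer count of stable fixed points.
#' @export
count_stable_fixed_points <- function(params, n_starts = 50L, seed = 1L) {
  sum(find_fixed_points(params, n_starts = n_starts, seed = seed)$stable)
}

#' Label the intermediate fixed point
#'
#' Among the stable fixed points, the "intermediate" state is the one
#' minimizing `|P_A - P_B|` (ties broken by lowest `prot_A`).
#'
#' @param fp A `caa_fixed_points` data frame.
#' @return Row index of the intermediate stable fixed point, or `NA_integer_`
#'   if there is no stable point.
#' @export
intermediate_fixed_point <- function(fp) {
  stable <- which(fp$stable)
  if (!length(stable)) return(NA_integer_)
  gap <- abs(fp$prot_A[stable] - fp$prot_B[stable])
  stable[order(gap, fp$prot_A[stable])][1L]
}
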