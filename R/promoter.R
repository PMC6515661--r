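#' Number of states of a single operator site
#'
#' An operator site is unbound, bound by an activator, or bound by a
#' repressor.
#'
#' @return `3L`.
#' @export
count_site_states <- function() 3L

#' Number of configurations of an m-operator promoter
#'
#' Sites are distinguishable and each takes one of [count_site_states()]
#' states, so a promoter with `m` tandem operator sites has `3^m`
#' configurations (e.g. 2187 for a 7-site tetO array).
#'
#' @param m Non-negative site count.
#' @return `3^m` as a double (exact for all practically relevant `m`).
#' @export
count_configurations <- function(m) {
  if (length(m) != 1L || is.na(m) || m < 0 || m != floor(m)) {
    stop("m must be a single non-negative integer", call. = FALSE)
  }
  3^m
}

#' Equilibrium occupancy distribution of an m-operator promoter
#'
#' Sites are independent and identical (tandem repeats, no cooperativity).
#' Each site is unbound, activator-bound or repressor-bound with
#' probabilities proportional to `1 : act_conc/K_act : rep_conc/K_rep`, so the
#' joint counts `(n_act, n_rep)` follow a multinomial law.
#'
#' @param m Site count (>= 0).
#' @param act_conc,rep_conc Activator / repressor concentrations (>= 0,
#'   arbitrary units matching the `K`s).
#' @param K_act,K_rep Dissociation constants (> 0).
#' @return Object of class `caa_occupancy`: `m`, per-site probabilities
#'   `p_site = c(unbound, activator, repressor)`, and `prob`, an
#'   `(m+1) x (m+1)` matrix with `prob[i, j] = P(n_act = i-1, n_rep = j-1)`
#'   (0 for infeasible pairs); entries sum to 1.
#' @examples
#' occupancy_distribution(1, 1, 1, 1, 1)$p_site  # (1/3, 1/3, 1/3)
#' @export
occupancy_distribution <- function(m, act_conc, rep_conc, K_act, K_rep) {
  if (m < 0 || m != floor(m)) stop("m must be a non-negative integer",
                                   call. = FALSE)
  stopifnot(act_conc >= 0, rep_conc >= 0, K_act > 0, K_rep > 0)
  w <- c(1, act_conc / K_act, rep_conc / K_rep)
  if (!all(is.finite(w)) || sum(w) <= 0) {
    stop("degenerate occupancy weights: all statistical weights vanish",
         call. = FALSE)
  }
  p <- w / sum(w)
  prob <- matrix(0, nrow = m + 1L, ncol = m + 1L,
                 dimnames = list(n_act = 0:m, n_rep = 0:m))
  for (na in 0:m) {
    for (nr in 0:(m - na)) {
      prob[na + 1L, nr + 1L] <- exp(
        lgamma(m + 1) - lgamma(na + 1) - lgamma(nr + 1) -
          lgamma(m - na - nr + 1)
      ) * p[2]^na * p[3]^nr * p[1]^(m - na - nr)
    }
  }
  structure(list(m = m, p_site = stats::setNames(p, c("unbound", "activator",
                                                      "repressor")),
                 prob = prob),
            class = "caa_occupancy")
}

#' Default winner-take-most promoter activity function
#'
#' Activity of a configuration `(n_act, n_rep)` of an `m`-site promoter:
#' activation raises the rate linearly in the bound-activator fraction,
#' `alpha_basal + (alpha_active - alpha_basal) * n_act / m`, and repression
#' multiplies it by `(1 - n_rep/m) * (1 - strength) + strength * [n_rep == 0]`.
#' `strength = 1` means any bound repressor silences the promoter (dominant
#' repression); `strength = 0` means repression only dilutes activity in
#' proportion to occupied sites (graded). The default `strength = 0.3`
#' (partial dominance) is the regime in which adding operator sites both
#' shrinks the configurational activity variance and flattens the expected
#' dose response — the averaging effect; at `strength = 1` every promoter is
#' all-or-none in repressor occupancy regardless of `m`, which removes the
#' effect.
#'
#' @param alpha_basal,alpha_active Transcription rates (per hour).
#' @param strength Repression dominance in `[0, 1]` (default 0.3).
#' @return A function `f(n_act, n_rep, m)` returning a non-negative rate.
#' @export
promoter_activity_fn <- function(alpha_basal = 1.5, alpha_active = 60,
                                 strength = 0.3) {
  stopifnot(strength >= 0, strength <= 1, alpha_basal >= 0,
            alpha_active >= alpha_basal)
  function(n_act, n_rep, m) {
    base <- alpha_basal + (alpha_active - alpha_basal) * n_act / m
    base * ((1 - n_rep / m) * (1 - strength) + strength * (n_rep == 0))
  }
}

#' Expected promoter activity under the occupancy distribution
#'
#' @inheritParams occupancy_distribution
#' @param activity_fn Function `(n_act, n_rep, m) -> rate` (see
#'   [promoter_activity_fn()]).
#' @return Expected activity (scalar).
#' @export
expected_activity <- function(m, act_conc, rep_conc, K_act, K_rep,
                              activity_fn = promoter_activity_fn()) {
  od <- occupancy_distribution(m, act_conc, rep_conc, K_act, K_rep)
  total <- 0
  for (na in 0:m) {
    for (nr in 0:(m - na)) {
      pr <- od$prob[na + 1L, nr + 1L]
      if (pr > 0) {
        a <- activity_fn(na, nr, m)
        if (a < 0) stop("activity_fn returned a negative rate", call. = FALSE)
        total <- total + pr * a
      }
    }
  }
  total
}

#' Expected activity along a concentration-ratio scan
#'
#' Scans `log10(act_conc / rep_conc)` at fixed total concentration and
#' returns the dose-response of the expected activity — the quantity whose
#' steepness distinguishes switch-like (few sites) from graded (many sites)
#' promoters.
#'
#' @param m Site count.
#' @param log_ratio Numeric vector of `log10(act/rep)` values.
#' @param total_conc Combined concentration `act + rep` (units of the `K`s).
#' @param K_act,K_rep Dissociation constants.
#' @param activity_fn Configuration activity function.
#' @return `data.frame` with `log_ratio` and `activity`.
#' @export
activity_scan <- function(m, log_ratio = seq(-2, 2, by = 0.05),
                          total_conc = 10, K_act = 1, K_rep = 1,
                          activity_fn = promoter_activity_fn()) {
  act <- total_conc * 10^log_ratio / (1 + 10^log_ratio)
  rep_ <- total_conc - act
  activity <- vapply(seq_along(log_ratio), function(i) {
    expected_activity(m, act[i], rep_[i], K_act, K_rep, activity_fn)
  }, numeric(1))
  data.frame(log_ratio = log_ratio, activity = activity)
}

#' Maximum slope of the expected-activity dose response
#'
#' Central-difference estimate of `max |d activity / d log10(act/rep)|` over
#' the scan; smaller values mean a more graded (less switch-like) promoter.
#'
#' @inheritParams activity_scan
#' @return Scalar maximum absolute slope.
#' @export
max_activity_slope <- function(m, log_ratio = seq(-2, 2, by = 0.05),
                               total_conc = 10, K_act = 1, K_rep = 1,
                               activity_fn = promoter_activity_fn()) {
  sc <- activity_scan(m, log_ratio, total_conc, K_act, K_rep, activity_fn)
  max(abs(diff(sc$activity) / diff(sc$log_ratio)))
}
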