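#' Exact stochastic simulation of a CAA network
#'
#' Gillespie direct-method SSA. The random stream is R's default
#' Mersenne-Twister generator, seeded with `seed` immediately before the run,
#' so identical `(network, initial, t_end, seed)` give bit-identical
#' trajectories.
#'
#' @param network A [build_network()] object.
#' @param initial Initial count vector aligned to `network$species`; defaults
#'   to [initial_state()] (all promoters free, zero mRNA and protein).
#' @param t_end Simulation horizon in hours (default 16, the experimental
#'   endpoint the package mirrors).
#' @param seed Integer RNG seed.
#' @param record If `TRUE` (default) the full event history is kept; set
#'   `FALSE` for endpoint-only runs (used by [endpoint_ensemble()]).
#' @param max_events Guard against runaway simulations.
#' @return An object of class `caa_trajectory`: `times` (event times, starting
#'   at 0), `states` (events x species matrix, first row = initial state),
#'   `final` (named state at `t_end`), `t_end`, `seed`, `n_events`, `species`.
#'   With `record = FALSE`, `times`/`states` are `NULL`.
#' @examples
#' net <- build_network(default_parameters("strong"))
#' tr <- simulate_circuit(net, t_end = 2, seed = 1)
#' tr$final
#' @export
simulate_circuit <- function(network, initial = initial_state(network),
                             t_end = 16, seed = 1L, record = TRUE,
                             max_events = 2e7) {
  stopifnot(inherits(network, "caa_network"), t_end > 0)
  initial <- check_state(network, initial)
  set.seed(as.integer(seed))
  res <- .ssa_run(network$stoich, network$rate_constants,
                  lapply(network$factors, function(f) as.integer(f[, 1L])),
                  lapply(network$factors, function(f) as.integer(f[, 2L])),
                  as.numeric(initial), t_end, record, max_events)
  out <- list(
    times = if (record) res$times else NULL,
    states = if (record) {
      m <- t(res$states)
      colnames(m) <- network$species
      m
    } else NULL,
    final = stats::setNames(res$final, network$species),
    t_end = t_end,
    seed = as.integer(seed),
    n_events = res$n_events,
    species = network$species
  )
  class(out) <- "caa_trajectory"
  out
}

check_state <- function(network, state) {
  if (length(state) != length(network$species)) {
    stop("initial state must have ", length(network$species), " entries",
         call. = FALSE)
  }
  if (any(state < 0) || any(!is.finite(state))) {
    stop("initial state must be finite and non-negative", call. = FALSE)
  }
  for (cons in network$conservation) {
    if (sum(state[cons$species]) != cons$total) {
      stop("initial promoter-state counts must sum to the side's copy number",
           call. = FALSE)
    }
  }
  stats::setNames(as.numeric(state), network$species)
}

#' Ensemble of independent endpoint states
#'
#' Runs `n_runs` independent simulations with seeds `base_seed`,
#' `base_seed + 1`, ..., `base_seed + n_runs - 1` and collects the state at
#' `t_end` of each (state at the last event carried forward — an endpoint
#' sample, not a time average).
#'
#' @inheritParams simulate_circuit
#' @param n_runs Number of independent runs (>= 1).
#' @param base_seed Seed of the first run.
#' @return Matrix `n_runs` x species of endpoint counts, with a `seeds`
#'   attribute.
#' @examples
#' net <- build_network(default_parameters("strong"))
#' ep <- endpoint_ensemble(net, t_end = 2, n_runs = 5, base_seed = 1)
#' dim(ep)
#' @export
endpoint_ensemble <- function(network, initial = initial_state(network),
                              t_end = 16, n_runs = 1000L, base_seed = 1L,
                              max_events = 2e7) {
  stopifnot(n_runs >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  out <- matrix(0, nrow = n_runs, ncol = length(network$species),
                dimnames = list(NULL, network$species))
  for (i in seq_len(n_runs)) {
    out[i, ] <- simulate_circuit(network, initial, t_end, seeds[i],
                                 record = FALSE, max_events = max_events)$final
  }
  attr(out, "seeds") <- seeds
  attr(out, "t_end") <- t_end
  out
}

#' Trajectory as a data frame
#'
#' @param x A recorded `caa_trajectory`.
#' @param ... Unused.
#' @return `data.frame` with a `time` column plus one column per species.
#' @export
as.data.frame.caa_trajectory <- function(x, ...) {
  if (is.null(x$times)) {
    stop("trajectory was run with record = FALSE", call. = FALSE)
  }
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' @export
print.caa_trajectory <- function(x, ...) {
  cat("CAA trajectory: ", x$n_events, " events over [0, ", x$t_end,
      "] h (seed ", x$seed, ")\n", sep = "")
  cat("final state:\n")
  print(x$final)
  invisible(x)
}

#' Write a recorded trajectory as CSV
#'
#' @param trajectory A recorded `caa_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
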