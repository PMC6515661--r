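QUADRANTS <- c("A_exclusive", "B_exclusive", "double_high", "double_low")

#' Expression-quadrant thresholds
#'
#' @param theta_A,theta_B Positive protein-count cutoffs separating "high"
#'   from "low" per side.
#' @return An object of class `caa_thresholds`.
#' @export
thresholds <- function(theta_A, theta_B = theta_A) {
  stopifnot(theta_A > 0, theta_B > 0)
  structure(list(theta_A = theta_A, theta_B = theta_B),
            class = "caa_thresholds")
}

#' Self-calibrating quadrant thresholds from the mean-field fixed points
#'
#' When the mean-field system has at least two stable fixed points with
#' distinct protein levels, the per-side threshold is the geometric mean of
#' the lowest and highest stable fixed-point protein value (which places it
#' strictly between the "low" and "high" states). For a monostable parameter
#' set it falls back to ten times the basal expression level,
#' `10 * alpha_basal * beta / (delta_m * delta_p)`.
#'
#' @param params A [circuit_parameters()] object.
#' @param fp Optionally, a precomputed [find_fixed_points()] result.
#' @return A `caa_thresholds` object.
#' @export
default_thresholds <- function(params, fp = find_fixed_points(params)) {
  fallback <- 10 * params$alpha_basal * params$beta /
    (params$delta_m * params$delta_p)
  th <- function(v) {
    v <- v[fp$stable]
    if (length(v) >= 2 && max(v) > min(v) * (1 + 1e-6) && min(v) > 0) {
      sqrt(min(v) * max(v))
    } else {
      fallback
    }
  }
  thresholds(th(fp$prot_A), th(fp$prot_B))
}

#' Classify endpoint states into expression quadrants
#'
#' Compares protein counts against the thresholds; exact equality counts as
#' "high".
#'
#' @param state A named endpoint state vector (with `protA`, `protB`), a
#'   matrix of such rows (e.g. from [endpoint_ensemble()]), or a length-2
#'   vector `(P_A, P_B)`.
#' @param thresholds A `caa_thresholds` object.
#' @return Factor with levels `A_exclusive`, `B_exclusive`, `double_high`,
#'   `double_low`.
#' @examples
#' classify_endpoint(c(100, 1), thresholds(10))
#' @export
classify_endpoint <- function(state, thresholds) {
  stopifnot(inherits(thresholds, "caa_thresholds"))
  if (is.matrix(state)) {
    PA <- state[, "protA"]; PB <- state[, "protB"]
  } else if (!is.null(names(state)) && all(c("protA", "protB") %in% names(state))) {
    PA <- state[["protA"]]; PB <- state[["protB"]]
  } else if (length(state) == 2L) {
    PA <- state[[1L]]; PB <- state[[2L]]
  } else {
    stop("state must name protA/protB or be a length-2 (P_A, P_B) vector",
         call. = FALSE)
  }
  hiA <- PA >= thresholds$theta_A
  hiB <- PB >= thresholds$theta_B
  lab <- ifelse(hiA & hiB, "double_high",
         ifelse(hiA, "A_exclusive",
         ifelse(hiB, "B_exclusive", "double_low")))
  factor(lab, levels = QUADRANTS)
}

#' Quadrant summary of one endpoint ensemble
#'
#' @param endpoints Matrix from [endpoint_ensemble()].
#' @param thresholds A `caa_thresholds`.
#' @return Named numeric vector of quadrant fractions (sums to 1).
#' @export
quadrant_fractions <- function(endpoints, thresholds) {
  lab <- classify_endpoint(endpoints, thresholds)
  table(lab) / nrow(endpoints)
}

#' Stochastic dosage sweep over promoter copy numbers
#'
#' For each `(copies_A, copies_B)` pair, runs an endpoint ensemble of the CAA
#' network at those copy numbers and summarizes the fractions of runs landing
#' in each expression quadrant — the computational dosage-versus-exclusivity
#' experiment. Thresholds are computed once from `params` at single-copy
#' promoters so that all grid cells are classified on a common scale.
#'
#' @param params Base parameter set (its copy numbers are overridden cell by
#'   cell).
#' @param copy_grid Two-column matrix or data frame of copy-number pairs, or a
#'   list of length-2 vectors. Default: the full 5 x 5 grid.
#' @param n_runs Runs per grid cell (>= 100 for meaningful fractions).
#' @param t_end Horizon in hours.
#' @param base_seed Seed of the first run of the first cell; cells use
#'   disjoint consecutive seed blocks so the whole sweep is reproducible.
#' @param thresholds Optional `caa_thresholds` override.
#' @return `data.frame` of class `caa_sweep`: `copies_A`, `copies_B`,
#'   `n_runs`, and fractions `A_exclusive`, `B_exclusive`, `double_high`,
#'   `double_low` (each row sums to 1).
#' @examples
#' \donttest{
#' sw <- dosage_sweep(default_parameters("strong"),
#'                    copy_grid = cbind(c(1, 5), c(1, 5)), n_runs = 100)
#' }
#' @export
dosage_sweep <- function(params,
                         copy_grid = as.matrix(expand.grid(copies_A = 1:5,
                                                           copies_B = 1:5)),
                         n_runs = 1000L, t_end = 16, base_seed = 1L,
                         thresholds = NULL) {
  validate_parameters(params)
  stopifnot(n_runs >= 100L)
  if (is.list(copy_grid) && !is.data.frame(copy_grid)) {
    copy_grid <- do.call(rbind, copy_grid)
  }
  copy_grid <- as.matrix(copy_grid)
  stopifnot(ncol(copy_grid) == 2L, all(copy_grid >= 1L))

  if (is.null(thresholds)) {
    base <- params; base$copies_A <- 1L; base$copies_B <- 1L
    thresholds <- default_thresholds(base)
  }

  rows <- vector("list", nrow(copy_grid))
  for (i in seq_len(nrow(copy_grid))) {
    p <- params
    p$copies_A <- as.integer(copy_grid[i, 1L])
    p$copies_B <- as.integer(copy_grid[i, 2L])
    net <- build_network(p)
    cell_seed <- as.integer(base_seed) + (i - 1L) * as.integer(n_runs)
    ep <- tryCatch(
      endpoint_ensemble(net, t_end = t_end, n_runs = n_runs,
                        base_seed = cell_seed),
      error = function(e) {
        stop("dosage_sweep failed at grid cell (", p$copies_A, ", ",
             p$copies_B, "): ", conditionMessage(e), call. = FALSE)
      })
    fr <- quadrant_fractions(ep, thresholds)
    rows[[i]] <- data.frame(copies_A = p$copies_A, copies_B = p$copies_B,
                            n_runs = as.integer(n_runs),
                            A_exclusive = fr[["A_exclusive"]],
                            B_exclusive = fr[["B_exclusive"]],
                            double_high = fr[["double_high"]],
                            double_low = fr[["double_low"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("caa_sweep", "data.frame")
  out
}

#' Plot a dosage sweep as a grid of quadrant-fraction pies
#'
#' Thin optional visualization (requires ggplot2): one pie per copy-number
#' combination, green = A-exclusive, red = B-exclusive, yellow = both high,
#' grey = both low.
#'
#' @param sweep A [dosage_sweep()] result.
#' @return A ggplot object.
#' @export
plot_dosage_sweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dosage_sweep requires ggplot2", call. = FALSE)
  }
  long <- do.call(rbind, lapply(QUADRANTS, function(q) {
    data.frame(copies_A = sweep$copies_A, copies_B = sweep$copies_B,
               quadrant = q, fraction = sweep[[q]])
  }))
  long$quadrant <- factor(long$quadrant, levels = QUADRANTS)
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = fraction, fill = quadrant)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_grid(copies_B ~ copies_A, as.table = FALSE,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(A_exclusive = "forestgreen",
                                          B_exclusive = "firebrick",
                                          double_high = "gold",
                                          double_low = "grey70")) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "endpoint quadrant")
}
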