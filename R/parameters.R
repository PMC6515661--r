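#' Kinetic parameters of the CAA circuit
#'
#' Bundles every rate constant and architectural setting of the
#' cross-antagonism-with-autoregulation (CAA) circuit: two transcription
#' factors, each activating its own promoter and repressing the opposite one.
#' Activator and repressor bind the shared operator competitively and act as
#' homodimers, so binding propensities are second order in protein count
#' (`k_on * P^2` per free promoter copy). All rates are per hour; time is
#' measured in hours throughout the package.
#'
#' @param copies_A,copies_B Integer promoter (gene) copy number per side.
#' @param operator_sites Operator sites per promoter (`m`). The stochastic
#'   engine always uses the three-state aggregate promoter; the explicit
#'   multi-site occupancy model lives in [occupancy_distribution()] and
#'   [expected_activity()].
#' @param k_act_on Activator (dimer) binding rate, per molecule^2 per hour.
#' @param k_act_off Activator unbinding rate, per hour.
#' @param k_rep_on Repressor (dimer) binding rate, per molecule^2 per hour.
#' @param k_rep_off Repressor unbinding rate, per hour.
#' @param alpha_active Transcription rate of an activator-bound promoter copy
#'   (mRNA per hour).
#' @param alpha_basal Transcription rate of an unbound promoter copy.
#' @param alpha_repressed Transcription rate of a repressor-bound promoter
#'   copy (0 under strong repression, a basal leak under weak repression).
#' @param beta Translation rate (protein per mRNA per hour).
#' @param delta_m mRNA degradation rate, per hour.
#' @param delta_p Protein degradation/dilution rate, per hour.
#' @param repression_mode `"strong"` (repressor silences: `alpha_repressed`
#'   must be 0 and `k_rep_off <= k_act_off`) or `"weak"` (steric occlusion
#'   with leak: `alpha_repressed > 0`).
#'
#' @return An object of class `caa_params` (a named list).
#' @seealso [default_parameters()], [build_network()], [find_fixed_points()]
#' @examples
#' p <- circuit_parameters(copies_A = 2, copies_B = 1)
#' p$copies_A
#' @export
circuit_parameters <- function(copies_A = 1L,
                               copies_B = 1L,
                               operator_sites = 1L,
                               k_act_on = 0.02,
                               k_act_off = 2,
                               k_rep_on = 6.25e-4,
                               k_rep_off = 1,
                               alpha_active = 60,
                               alpha_basal = 1.5,
                               alpha_repressed = 0,
                               beta = 7,
                               delta_m = 3.5,
                               delta_p = 0.7,
                               repression_mode = c("strong", "weak")) {
  repression_mode <- match.arg(repression_mode)
  p <- list(
    copies_A = as.integer(copies_A), copies_B = as.integer(copies_B),
    operator_sites = as.integer(operator_sites),
    k_act_on = k_act_on, k_act_off = k_act_off,
    k_rep_on = k_rep_on, k_rep_off = k_rep_off,
    alpha_active = alpha_active, alpha_basal = alpha_basal,
    alpha_repressed = alpha_repressed,
    beta = beta, delta_m = delta_m, delta_p = delta_p,
    repression_mode = repression_mode
  )
  class(p) <- "caa_params"
  validate_parameters(p)
  p
}

#' Validate a CAA parameter set
#'
#' Checks every structural invariant of [circuit_parameters()] and fails with
#' an error naming the offending field.
#'
#' @param params A `caa_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "caa_params"))
  rate_fields <- c("k_act_on", "k_act_off", "k_rep_on", "k_rep_off",
                   "alpha_active", "alpha_basal", "alpha_repressed",
                   "beta", "delta_m", "delta_p")
  for (f in rate_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("invalid parameter '", f, "': must be a single finite rate >= 0",
           call. = FALSE)
    }
  }
  for (f in c("copies_A", "copies_B")) {
    if (is.na(params[[f]]) || params[[f]] < 1L) {
      stop("invalid parameter '", f, "': promoter copy number must be >= 1",
           call. = FALSE)
    }
  }
  if (is.na(params$operator_sites) || params$operator_sites < 1L) {
    stop("invalid parameter 'operator_sites': must be >= 1", call. = FALSE)
  }
  if (params$alpha_repressed > params$alpha_basal) {
    stop("invalid parameter 'alpha_repressed': must be <= alpha_basal",
         call. = FALSE)
  }
  if (params$alpha_basal > params$alpha_active) {
    stop("invalid parameter 'alpha_basal': must be <= alpha_active",
         call. = FALSE)
  }
  if (identical(params$repression_mode, "strong")) {
    if (params$alpha_repressed != 0) {
      stop("invalid parameter 'alpha_repressed': must be 0 in strong mode",
           call. = FALSE)
    }
    if (params$k_rep_off > params$k_act_off) {
      stop("invalid parameter 'k_rep_off': must be <= k_act_off in strong mode",
           call. = FALSE)
    }
  } else {
    if (params$alpha_repressed <= 0) {
      stop("invalid parameter 'alpha_repressed': must be > 0 in weak mode",
           call. = FALSE)
    }
  }
  invisible(params)
}

#' Default symmetric parameter sets for strong and weak repression
#'
#' The strong set makes the mean-field reduction tristable (two exclusive
#' states plus a stable symmetric co-expression state, see
#' [count_stable_fixed_points()]); the weak set — basal leak through the
#' repressor-bound promoter (30% of basal) together with a ten-fold faster
#' repressor off-rate — is monostable. Promoter switching is slow relative to
#' active transcription (`k_act_off`, `k_rep_off` << `alpha_active`) so the
#' stochastic model bursts.
#'
#' @param mode `"strong"` or `"weak"`.
#' @param ... Overrides passed on to [circuit_parameters()] (e.g.
#'   `copies_A = 3`).
#' @return A `caa_params` object.
#' @examples
#' count_stable_fixed_points(default_parameters("strong"))
#' @export
default_parameters <- function(mode = c("strong", "weak"), ...) {
  mode <- match.arg(mode)
  if (mode == "strong") {
    circuit_parameters(repression_mode = "strong", ...)
  } else {
    circuit_parameters(repression_mode = "weak",
                       alpha_repressed = 0.45,
                       k_rep_off = 10, ...)
  }
}

#' Interpolate between strong and beyond-weak repression
#'
#' One-dimensional slice through parameter space used to study how the number
#' of stable states collapses as repression is attenuated: the repressed-state
#' leak rises linearly, `alpha_repressed = s * alpha_basal`, while the
#' repressor off-rate weakens geometrically, `k_rep_off = k0 * 10^s`. At
#' `s = 0` this is the strong default; `s = 0.3` matches the weak default's
#' leak and lies past its stability boundary; at `s = 1` repression is fully
#' leaky and loose.
#'
#' @param s Slice coordinate in `[0, 1]` (the ratio
#'   `alpha_repressed / alpha_basal`).
#' @param base A strong-mode `caa_params` to start from.
#' @return A `caa_params` object (mode `"weak"` for `s > 0`).
#' @export
repression_slice <- function(s, base = default_parameters("strong")) {
  stopifnot(s >= 0, s <= 1)
  if (s == 0) return(base)
  args <- unclass(base)
  args$repression_mode <- "weak"
  args$alpha_repressed <- s * base$alpha_basal
  args$k_rep_off <- base$k_rep_off * 10^s
  do.call(circuit_parameters, args)
}

#' @export
print.caa_params <- function(x, ...) {
  cat("CAA circuit parameters (", x$repression_mode, " repression)\n", sep = "")
  cat("  copies: A =", x$copies_A, ", B =", x$copies_B,
      "; operator sites m =", x$operator_sites, "\n")
  cat(sprintf("  binding  : k_act_on = %g, k_act_off = %g, k_rep_on = %g, k_rep_off = %g\n",
              x$k_act_on, x$k_act_off, x$k_rep_on, x$k_rep_off))
  cat(sprintf("  expression: alpha (active/basal/repressed) = %g/%g/%g, beta = %g\n",
              x$alpha_active, x$alpha_basal, x$alpha_repressed, x$beta))
  cat(sprintf("  turnover : delta_m = %g /h, delta_p = %g /h\n",
              x$delta_m, x$delta_p))
  invisible(x)
}

#' Read / write circuit parameters as YAML
#'
#' Plain YAML files whose keys mirror the fields of [circuit_parameters()].
#'
#' @param path File path.
#' @param params A `caa_params` object.
#' @return `read_circuit_parameters()` returns a validated `caa_params`;
#'   `write_circuit_parameters()` returns `path` invisibly.
#' @export
read_circuit_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(circuit_parameters)))
  if (length(unknown)) {
    stop("unknown parameter field(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(circuit_parameters, vals)
}

#' @rdname read_circuit_parameters
#' @export
write_circuit_parameters <- function(params, path) {
  validate_parameters(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
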