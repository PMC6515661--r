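#' Build the CAA reaction network
#'
#' Realizes the circuit as a mass-action reaction network over 10 species:
#' per side, three aggregate promoter-state counts (free, activator-bound,
#' repressor-bound, summing to the side's copy number), one mRNA pool and one
#' protein pool. Per side the reactions are: activator binding
#' (`k_act_on * P_self^2` per free copy) and unbinding; repressor binding
#' (`k_rep_on * P_opposite^2` per free copy) and unbinding; transcription from
#' each promoter state at its `alpha`; translation at `beta` per mRNA; and
#' first-order degradation of mRNA and protein. Binding is non-sequestering
#' (protein counts are not decremented on binding). Reactions whose rate
#' constant is exactly zero are pruned, so the strong-repression defaults
#' yield 18 reactions and a fully leaky parameter set yields 20.
#'
#' @param params A validated [circuit_parameters()] object.
#' @return An object of class `caa_network` with elements `species`
#'   (character), `stoich` (species x reactions integer matrix),
#'   `rate_constants`, `reaction_names`, `factors` (per reaction, a
#'   two-column matrix of (species index, exponent) giving the propensity
#'   monomial), `conservation` (list of species-index groups with their
#'   conserved totals) and `params`.
#' @examples
#' net <- build_network(default_parameters("strong"))
#' length(net$species)      # 10
#' ncol(net$stoich)         # 18
#' @export
build_network <- function(params) {
  validate_parameters(params)
  species <- c("proA_free", "proA_act", "proA_rep", "mrnaA", "protA",
               "proB_free", "proB_act", "proB_rep", "mrnaB", "protB")
  idx <- stats::setNames(seq_along(species), species)

  rxn <- list()
  add <- function(name, k, changes, factors) {
    s <- integer(length(species))
    s[idx[names(changes)]] <- changes
    rxn[[length(rxn) + 1L]] <<- list(name = name, k = k, stoich = s,
                                     factors = factors)
  }
  mono <- function(...) {
    f <- list(...)
    m <- do.call(rbind, lapply(f, function(x) c(idx[[x[[1]]]], x[[2]])))
    colnames(m) <- c("species", "exponent")
    m
  }

  for (side in c("A", "B")) {
    opp <- if (side == "A") "B" else "A"
    pf <- paste0("pro", side, "_free"); pa <- paste0("pro", side, "_act")
    pr <- paste0("pro", side, "_rep")
    mr <- paste0("mrna", side); pt <- paste0("prot", side)
    po <- paste0("prot", opp)

    add(paste0("bind_act_", side), params$k_act_on,
        stats::setNames(c(-1L, 1L), c(pf, pa)),
        mono(list(pt, 2L), list(pf, 1L)))
    add(paste0("unbind_act_", side), params$k_act_off,
        stats::setNames(c(1L, -1L), c(pf, pa)),
        mono(list(pa, 1L)))
    add(paste0("bind_rep_", side), params$k_rep_on,
        stats::setNames(c(-1L, 1L), c(pf, pr)),
        mono(list(po, 2L), list(pf, 1L)))
    add(paste0("unbind_rep_", side), params$k_rep_off,
        stats::setNames(c(1L, -1L), c(pf, pr)),
        mono(list(pr, 1L)))
    add(paste0("tx_active_", side), params$alpha_active,
        stats::setNames(1L, mr), mono(list(pa, 1L)))
    add(paste0("tx_basal_", side), params$alpha_basal,
        stats::setNames(1L, mr), mono(list(pf, 1L)))
    add(paste0("tx_repressed_", side), params$alpha_repressed,
        stats::setNames(1L, mr), mono(list(pr, 1L)))
    add(paste0("translate_", side), params$beta,
        stats::setNames(1L, pt), mono(list(mr, 1L)))
    add(paste0("deg_mrna_", side), params$delta_m,
        stats::setNames(-1L, mr), mono(list(mr, 1L)))
    add(paste0("deg_prot_", side), params$delta_p,
        stats::setNames(-1L, pt), mono(list(pt, 1L)))
  }

  # prune zero-rate channels so the network carries only live reactions
  rxn <- Filter(function(r) r$k > 0, rxn)

  net <- list(
    species = species,
    stoich = do.call(cbind, lapply(rxn, `[[`, "stoich")),
    rate_constants = vapply(rxn, `[[`, numeric(1), "k"),
    reaction_names = vapply(rxn, `[[`, character(1), "name"),
    factors = lapply(rxn, `[[`, "factors"),
    conservation = list(
      list(species = idx[c("proA_free", "proA_act", "proA_rep")],
           total = params$copies_A),
      list(species = idx[c("proB_free", "proB_act", "proB_rep")],
           total = params$copies_B)
    ),
    params = params
  )
  rownames(net$stoich) <- species
  colnames(net$stoich) <- net$reaction_names
  class(net) <- "caa_network"
  net
}

#' Propensities of a network at a state
#'
#' Reference implementation of the propensity vector (the C++ engine computes
#' the same quantity event by event); used for validation and testing.
#'
#' @param network A `caa_network`.
#' @param state Named or unnamed count vector aligned to `network$species`.
#' @return Numeric vector, one propensity per reaction.
#' @export
propensities <- function(network, state) {
  stopifnot(length(state) == length(network$species))
  vapply(seq_along(network$rate_constants), function(j) {
    f <- network$factors[[j]]
    network$rate_constants[j] * prod(state[f[, 1L]]^f[, 2L])
  }, numeric(1))
}

#' Initial condition: all promoters free, no mRNA or protein
#'
#' @param network A `caa_network`.
#' @return Named integer count vector.
#' @export
initial_state <- function(network) {
  s <- stats::setNames(integer(length(network$species)), network$species)
  s["proA_free"] <- network$params$copies_A
  s["proB_free"] <- network$params$copies_B
  s
}

#' @export
print.caa_network <- function(x, ...) {
  cat("CAA reaction network:", length(x$species), "species,",
      length(x$rate_constants), "reactions\n")
  cat("  copies: A =", x$params$copies_A, ", B =", x$params$copies_B, "\n")
  invisible(x)
}
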