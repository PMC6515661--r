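#' Canonical quadrant population centers
#'
#' Centers of the four discrete expression populations in log10 fluorescence
#' (GFP, mCherry), spanning the decades typical of flow data: "low" at
#' `10^low` a.u. and "high" at `10^high` a.u.
#'
#' @param low,high Low / high log10 fluorescence levels.
#' @return Named list of length-2 vectors `(log10 GFP, log10 mCherry)` for
#'   `A_exclusive`, `B_exclusive`, `double_high`, `double_low`.
#' @export
quadrant_centers <- function(low = 2, high = 4) {
  list(A_exclusive = c(high, low),
       B_exclusive = c(low, high),
       double_high = c(high, high),
       double_low  = c(low, low))
}

#' Specification of one expression population
#'
#' A bivariate log-normal cloud of events: log10 fluorescence is normal with
#' the given center and per-channel spread.
#'
#' @param center_gfp,center_mcherry Population center in log10 a.u.
#' @param spread Per-channel standard deviation in log10 units (default 0.15,
#'   a tight flow-cytometry population).
#' @param weight Fraction of the clone's events drawn from this population.
#' @return Object of class `caa_population`.
#' @export
population_spec <- function(center_gfp, center_mcherry, spread = 0.15,
                            weight = 1) {
  stopifnot(spread >= 0, weight >= 0)
  structure(list(center = c(gfp = center_gfp, mcherry = center_mcherry),
                 spread = spread, weight = weight),
            class = "caa_population")
}

#' Specification of one synthetic clone
#'
#' @param clone_id Identifier.
#' @param populations List of 1-4 [population_spec()]s; weights are
#'   normalized to sum to 1.
#' @param n_events Events to draw (>= 1; default 20000 per clone).
#' @param seed RNG seed for this clone.
#' @return Object of class `caa_clone_spec`.
#' @export
clone_spec <- function(clone_id, populations, n_events = 20000L, seed = 1L) {
  stopifnot(length(populations) >= 1L, length(populations) <= 4L,
            n_events >= 1L)
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("population weights must sum to > 0", call. = FALSE)
  for (i in seq_along(populations)) populations[[i]]$weight <- w[i] / sum(w)
  structure(list(clone_id = as.character(clone_id),
                 populations = populations,
                 n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "caa_clone_spec")
}

#' Generate a synthetic clone response profile
#'
#' Draws `n_events` events: the population is chosen by weight, then the
#' event is bivariate log-normal around the population center. Deterministic
#' given the spec's seed.
#'
#' @param spec A [clone_spec()].
#' @return A [response_profile()].
#' @export
generate_clone_profile <- function(spec) {
  stopifnot(inherits(spec, "caa_clone_spec"))
  set.seed(spec$seed)
  w <- vapply(spec$populations, `[[`, numeric(1), "weight")
  pick <- sample.int(length(w), spec$n_events, replace = TRUE, prob = w)
  gfp <- numeric(spec$n_events)
  mch <- numeric(spec$n_events)
  for (p in seq_along(w)) {
    idx <- which(pick == p)
    if (!length(idx)) next
    pop <- spec$populations[[p]]
    gfp[idx] <- 10^stats::rnorm(length(idx), pop$center[["gfp"]], pop$spread)
    mch[idx] <- 10^stats::rnorm(length(idx), pop$center[["mcherry"]],
                                pop$spread)
  }
  response_profile(spec$clone_id, gfp, mch)
}

# Canonical ordering of the non-empty presence/absence patterns over the four
# quadrant populations: singletons, pairs, triples, then the full pattern.
presence_patterns <- function() {
  pats <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  pats <- as.matrix(pats[rowSums(pats) > 0, ])
  pats[order(rowSums(pats), apply(pats, 1L, function(r) {
    sum(r * 2^(0:3))
  })), , drop = FALSE]
}

#' Generate an archetype-labelled synthetic clone dataset
#'
#' Builds `k_archetypes` distinct clone layouts from the presence/absence
#' patterns of the four canonical quadrant populations (see
#' [enumerate_presence_patterns()]): singleton patterns first, then pairs,
#' triples and the full pattern; beyond 15 archetypes the patterns are reused
#' with skewed population weights. Each archetype is instantiated by
#' `clones_per_archetype` clones whose population centers are jittered
#' clone-by-clone.
#'
#' @param k_archetypes Number of archetypes (>= 2).
#' @param clones_per_archetype Clones per archetype.
#' @param n_events Events per clone.
#' @param jitter Clone-level center jitter (sd, log10 units).
#' @param spread Within-population event spread (log10 units).
#' @param seed Master seed; every clone derives its own seed from it.
#' @return List with `profiles` (list of [response_profile()]s), `labels`
#'   (true archetype index per profile) and `manifest` (data frame
#'   `clone_id`, `variant`, `file` — `file` filled in by
#'   [write_profiles()]).
#' @export
generate_archetype_dataset <- function(k_archetypes = 4L,
                                       clones_per_archetype = 25L,
                                       n_events = 20000L,
                                       jitter = 0.05, spread = 0.15,
                                       seed = 1L) {
  stopifnot(k_archetypes >= 2L, clones_per_archetype >= 1L)
  pats <- presence_patterns()
  centers <- quadrant_centers()
  set.seed(as.integer(seed))
  profiles <- list()
  labels <- integer(0)
  manifest <- list()
  clone_seeds <- as.integer(seed) + seq_len(k_archetypes *
                                              clones_per_archetype) * 101L
  ci <- 0L
  for (a in seq_len(k_archetypes)) {
    pat <- pats[((a - 1L) %% nrow(pats)) + 1L, ]
    present <- which(pat)
    # second cycle through the patterns: skew weights to keep archetypes apart
    w <- if (a <= nrow(pats) || length(present) == 1L) {
      rep(1 / length(present), length(present))
    } else {
      w0 <- c(3, rep(1, length(present) - 1L))
      w0 / sum(w0)
    }
    for (cl in seq_len(clones_per_archetype)) {
      ci <- ci + 1L
      jit <- stats::rnorm(2L * length(present), 0, jitter)
      pops <- lapply(seq_along(present), function(p) {
        ctr <- centers[[present[p]]] + jit[(2 * p - 1):(2 * p)]
        population_spec(ctr[1], ctr[2], spread = spread, weight = w[p])
      })
      id <- sprintf("arch%02d_clone%03d", a, cl)
      profiles[[ci]] <- generate_clone_profile(
        clone_spec(id, pops, n_events = n_events, seed = clone_seeds[ci]))
      labels[ci] <- a
      manifest[[ci]] <- data.frame(clone_id = id,
                                   variant = paste0("archetype_", a),
                                   file = NA_character_)
    }
  }
  list(profiles = profiles, labels = labels,
       manifest = do.call(rbind, manifest))
}

#' Write synthetic profiles to delimited text plus a manifest
#'
#' Emits one `<clone_id>.csv` event table per profile (columns `gfp`,
#' `mcherry`) and a `manifest.csv` (columns `clone_id`, `variant`, `file`) in
#' `dir` — exactly the format [load_profiles()] consumes.
#'
#' @param profiles List of [response_profile()]s.
#' @param dir Output directory (created if missing).
#' @param variants Optional variant labels (recycled).
#' @return Path to the manifest, invisibly.
#' @export
write_profiles <- function(profiles, dir, variants = NA_character_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  variants <- rep_len(variants, length(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    id <- attr(p, "clone_id")
    fn <- paste0(id, ".csv")
    utils::write.csv(data.frame(gfp = p$gfp, mcherry = p$mcherry),
                     file.path(dir, fn), row.names = FALSE)
    v <- attr(p, "variant")
    data.frame(clone_id = id,
               variant = if (is.na(variants[i]) && !is.null(v)) v
                         else variants[i],
               file = fn)
  })
  mfp <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), mfp, row.names = FALSE)
  invisible(mfp)
}

#' Simulate digital-PCR partition counts at a known copy number
#'
#' Reference positives are binomial with success probability
#' `1 - exp(-lambda_ref)`; the target uses `lambda = true_copies *
#' lambda_ref`.
#'
#' @param true_copies True target copies per genome (> 0).
#' @param lambda_ref Mean reference copies per partition (> 0).
#' @param total_partitions Partitions per reaction.
#' @param seed RNG seed.
#' @param target Target gene label.
#' @return List with `target` and `reference` [dpcr_measurement()]s.
#' @export
generate_dpcr_partitions <- function(true_copies, lambda_ref = 0.5,
                                     total_partitions = 20000L, seed = 1L,
                                     target = "GFP") {
  stopifnot(true_copies > 0, lambda_ref >= 0, total_partitions >= 1)
  set.seed(as.integer(seed))
  p_ref <- 1 - exp(-lambda_ref)
  p_tgt <- 1 - exp(-true_copies * lambda_ref)
  list(
    target = dpcr_measurement(target,
                              stats::rbinom(1L, total_partitions, p_tgt),
                              total_partitions),
    reference = dpcr_measurement("ALG9",
                                 stats::rbinom(1L, total_partitions, p_ref),
                                 total_partitions)
  )
}
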