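#' Two-channel response profile of one clone
#'
#' Per-event GFP / mCherry fluorescence of a single clonal culture (pre-gated
#' events; arbitrary units).
#'
#' @param clone_id Clone identifier.
#' @param gfp,mcherry Numeric event vectors of equal length (>= 1 event,
#'   finite).
#' @param variant Optional circuit-variant label.
#' @param timepoint Optional timepoint in hours.
#' @return Object of class `caa_profile`: a data frame of events with
#'   attributes `clone_id`, `variant`, `timepoint`.
#' @export
response_profile <- function(clone_id, gfp, mcherry, variant = NA_character_,
                             timepoint = NA_real_) {
  if (length(gfp) != length(mcherry)) {
    stop("gfp and mcherry must have the same length", call. = FALSE)
  }
  if (length(gfp) < 1L) stop("a profile needs at least one event",
                             call. = FALSE)
  if (!all(is.finite(gfp)) || !all(is.finite(mcherry))) {
    stop("fluorescence values must be finite", call. = FALSE)
  }
  structure(data.frame(gfp = as.numeric(gfp), mcherry = as.numeric(mcherry)),
            clone_id = as.character(clone_id), variant = variant,
            timepoint = timepoint,
            class = c("caa_profile", "data.frame"))
}

profile_meta <- function(p) {
  list(clone_id = attr(p, "clone_id"), variant = attr(p, "variant"),
       timepoint = attr(p, "timepoint"))
}

#' Trim outlier events from a profile
#'
#' Keeps events lying within the per-channel percentile bounds on both
#' channels (inclusive). Requesting an actual trim (`lower_pct > 0` or
#' `upper_pct < 100`) on a single-event profile is a degenerate-profile error,
#' as is trimming away every event.
#'
#' @param profile A [response_profile()].
#' @param lower_pct,upper_pct Percentile bounds, `0 <= lower < upper <= 100`.
#'   Default (0.5, 99.5).
#' @return The trimmed `caa_profile`.
#' @export
trim_outliers <- function(profile, lower_pct = 0.5, upper_pct = 99.5) {
  stopifnot(inherits(profile, "caa_profile"),
            lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  if (lower_pct == 0 && upper_pct == 100) return(profile)
  if (nrow(profile) < 2L) {
    stop("degenerate profile: cannot trim outliers from a single event",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(profile))
  for (ch in c("gfp", "mcherry")) {
    q <- stats::quantile(profile[[ch]], c(lower_pct, upper_pct) / 100,
                         names = FALSE)
    keep <- keep & profile[[ch]] >= q[1] & profile[[ch]] <= q[2]
  }
  if (!any(keep)) {
    stop("degenerate profile: all events trimmed", call. = FALSE)
  }
  meta <- profile_meta(profile)
  response_profile(meta$clone_id, profile$gfp[keep], profile$mcherry[keep],
                   meta$variant, meta$timepoint)
}

#' Pooled axis ranges for a set of profiles
#'
#' Computes global per-channel axis bounds from the pooled events (default
#' 0.1th-99.9th percentile), on the log10 scale if `log_transform`, so that
#' all profiles are binned on a common grid.
#'
#' @param profiles List of [response_profile()]s.
#' @param lower_pct,upper_pct Pooled percentile bounds.
#' @param log_transform Compute bounds on the log10 scale (values below
#'   `floor_au` are clamped to the floor first).
#' @param floor_au Positive floor (a.u.) applied before the log transform.
#' @return List with numeric `gfp` and `mcherry` ranges `c(min, max)`.
#' @export
profile_ranges <- function(profiles, lower_pct = 0.1, upper_pct = 99.9,
                           log_transform = TRUE, floor_au = 1) {
  pool <- function(ch) unlist(lapply(profiles, function(p) p[[ch]]),
                              use.names = FALSE)
  rng <- function(x) {
    if (log_transform) {
      if (any(x <= 0)) {
        stop(sum(x <= 0), " non-positive fluorescence value(s) under log ",
             "transform", call. = FALSE)
      }
      x <- log10(pmax(x, floor_au))
    }
    q <- stats::quantile(x, c(lower_pct, upper_pct) / 100, names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + 1e-6
    q
  }
  list(gfp = rng(pool("gfp")), mcherry = rng(pool("mcherry")))
}

#' Bin a profile into an n x n grid
#'
#' Equal-width bins on the (optionally log10) fluorescence scale. Bins are
#' half-open `[lo, hi)` with the last bin closed; out-of-range events are
#' clamped into the edge bins. Under the log transform, non-positive events
#' are an error and values in `(0, floor_au)` are clamped to `floor_au`.
#'
#' @param profile A [response_profile()].
#' @param n Bins per axis (>= 2). The package uses `n = 10` for clustering
#'   and `n = 100` for display.
#' @param ranges Axis ranges as returned by [profile_ranges()] (on the
#'   transformed scale when `log_transform = TRUE`).
#' @param log_transform Bin on the log10 scale (default `TRUE`).
#' @param normalize If `TRUE` (default) grid entries sum to 1; otherwise they
#'   are event counts.
#' @param floor_au Positive floor applied before the log transform.
#' @return Object of class `caa_binned`: `n`, `grid` (n x n matrix, GFP rows x
#'   mCherry columns), `ranges`, `normalized`, `clone_id`, `n_events`.
#' @export
bin_profile <- function(profile, n = 10L, ranges, log_transform = TRUE,
                        normalize = TRUE, floor_au = 1) {
  stopifnot(inherits(profile, "caa_profile"), n >= 2L)
  for (ch in c("gfp", "mcherry")) {
    r <- ranges[[ch]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2]) {
      stop("ranges$", ch, " must be finite with min < max", call. = FALSE)
    }
  }
  txf <- function(x) {
    if (!log_transform) return(x)
    if (any(x <= 0)) {
      stop(sum(x <= 0), " non-positive fluorescence value(s) under log ",
           "transform", call. = FALSE)
    }
    log10(pmax(x, floor_au))
  }
  bin_index <- function(x, r) {
    w <- (r[2] - r[1]) / n
    pmin(pmax(floor((x - r[1]) / w) + 1L, 1L), n)
  }
  i <- bin_index(txf(profile$gfp), ranges$gfp)
  j <- bin_index(txf(profile$mcherry), ranges$mcherry)
  grid <- matrix(tabulate((j - 1L) * as.integer(n) + i, nbins = n * n), n, n)
  grid <- grid + 0  # numeric, not integer
  if (normalize) grid <- grid / sum(grid)
  structure(list(n = as.integer(n), grid = grid, ranges = ranges,
                 normalized = normalize,
                 clone_id = attr(profile, "clone_id"),
                 n_events = nrow(profile)),
            class = "caa_binned")
}

#' Manhattan distance between two binned profiles
#'
#' Treats each grid as a vector and sums absolute cell differences. For
#' normalized profiles the distance lies in `[0, 2]`.
#'
#' @param p,q `caa_binned` objects on the same grid (same `n`, ranges and
#'   normalization).
#' @return Non-negative scalar.
#' @export
manhattan_distance <- function(p, q) {
  stopifnot(inherits(p, "caa_binned"), inherits(q, "caa_binned"))
  if (p$n != q$n || p$normalized != q$normalized ||
      !isTRUE(all.equal(p$ranges, q$ranges))) {
    stop("binned profiles are incompatible (different n, ranges or ",
         "normalization)", call. = FALSE)
  }
  sum(abs(p$grid - q$grid))
}

#' Pairwise Manhattan distance matrix
#'
#' @param binned List of compatible `caa_binned` objects.
#' @return Symmetric matrix with zero diagonal; dimnames are clone ids.
#' @export
profile_distance_matrix <- function(binned) {
  n <- length(binned)
  v <- do.call(cbind, lapply(binned, function(b) as.vector(b$grid)))
  for (b in binned[-1]) manhattan_distance(binned[[1]], b)  # compat check
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    di <- colSums(abs(v[, (i + 1L):n, drop = FALSE] - v[, i]))
    d[i, (i + 1L):n] <- di
    d[(i + 1L):n, i] <- di
  }
  ids <- vapply(binned, `[[`, character(1), "clone_id")
  dimnames(d) <- list(ids, ids)
  d
}

#' Partitioning around medoids (BUILD + SWAP with restarts)
#'
#' PAM on a precomputed dissimilarity matrix: greedy BUILD seeding followed
#' by exhaustive SWAP steps, accepting the best cost-reducing swap until none
#' remains. Because BUILD+SWAP can stall in local optima on small awkward
#' instances, the SWAP phase is re-run from `n_restarts - 1` additional
#' seeded random medoid sets and the cheapest solution is kept. All ties are
#' broken towards the lowest index and the restarts are drawn from `seed`, so
#' the result is fully reproducible.
#'
#' @param d Square symmetric non-negative dissimilarity matrix with zero
#'   diagonal.
#' @param k Number of clusters, `1 <= k <= nrow(d)`.
#' @param seed Seed for the restart draws.
#' @param n_restarts Total local-search starts (first one is BUILD).
#' @return Object of class `caa_pam`: `k`, `medoid_indices`, `assignments`
#'   (cluster index per point, clusters numbered by medoid order),
#'   `total_cost` (sum of distances to assigned medoids) and
#'   `mean_silhouette`.
#' @export
pam_cluster <- function(d, k, seed = 1L, n_restarts = 8L) {
  d <- as.matrix(d)
  N <- nrow(d)
  if (ncol(d) != N || any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop("d must be a square non-negative matrix with zero diagonal",
         call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) stop("d must be symmetric", call. = FALSE)
  if (k < 1L || k > N) stop("k must be between 1 and nrow(d)", call. = FALSE)

  cost_of <- function(med) sum(apply(d[, med, drop = FALSE], 1L, min))

  # SWAP local search: best strict improvement, lowest index wins ties by
  # scan order
  swap_descent <- function(medoids) {
    cost <- cost_of(medoids)
    repeat {
      best <- NULL
      best_cost <- cost
      for (mi in seq_along(medoids)) {
        for (h in seq_len(N)) {
          if (h %in% medoids) next
          cand <- medoids
          cand[mi] <- h
          cc <- cost_of(cand)
          if (cc < best_cost - 1e-12) {
            best <- cand
            best_cost <- cc
          }
        }
      }
      if (is.null(best)) break
      medoids <- best
      cost <- best_cost
    }
    list(medoids = sort(medoids), cost = cost)
  }

  # BUILD
  medoids <- unname(which.min(colSums(d)))
  while (length(medoids) < k) {
    dnear <- apply(d[, medoids, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(N), function(c) {
      if (c %in% medoids) return(-Inf)
      sum(pmax(0, dnear - d[, c]))
    }, numeric(1))
    medoids <- c(medoids, unname(which.max(gain)))
  }

  sol <- swap_descent(medoids)
  if (n_restarts > 1L && k < N) {
    set.seed(as.integer(seed))
    for (r in seq_len(n_restarts - 1L)) {
      cand <- swap_descent(sort(sample.int(N, k)))
      if (cand$cost < sol$cost - 1e-12) sol <- cand
    }
  }
  medoids <- sol$medoids
  # nearest medoid, ties to the lowest medoid index
  assign_idx <- apply(d[, medoids, drop = FALSE], 1L, which.min)
  res <- structure(list(k = as.integer(k),
                        medoid_indices = medoids,
                        assignments = as.integer(assign_idx),
                        total_cost = sum(d[cbind(seq_len(N),
                                                 medoids[assign_idx])]),
                        mean_silhouette = NA_real_),
                   class = "caa_pam")
  res$mean_silhouette <- mean(silhouette_widths(d, res$assignments))
  res
}

#' Silhouette widths
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)`; points in singleton
#' clusters score 0 by convention, as do points where both `a` and `b`
#' vanish. When there is a single cluster all widths are 0.
#'
#' @param d Dissimilarity matrix.
#' @param assignments Integer cluster labels.
#' @return Numeric vector of per-point widths in `[-1, 1]`.
#' @export
silhouette_widths <- function(d, assignments) {
  d <- as.matrix(d)
  N <- nrow(d)
  stopifnot(length(assignments) == N)
  clusters <- sort(unique(assignments))
  vapply(seq_len(N), function(i) {
    own <- assignments[i]
    mates <- which(assignments == own)
    if (length(mates) == 1L) return(0)
    a <- mean(d[i, setdiff(mates, i)])
    bs <- vapply(setdiff(clusters, own), function(cl) {
      mean(d[i, assignments == cl])
    }, numeric(1))
    if (!length(bs)) return(0)
    b <- min(bs)
    den <- max(a, b)
    if (den == 0) 0 else (b - a) / den
  }, numeric(1))
}

#' Scan bin counts and cluster numbers by silhouette
#'
#' Re-runs the bin -> Manhattan -> PAM pipeline over a grid of `n` (bins per
#' axis) and `k` (clusters) and reports the mean silhouette of each
#' combination; the recommended setting is the argmax, with ties resolved
#' towards smaller `k`, then smaller `n`.
#'
#' @param profiles List of (already trimmed) [response_profile()]s.
#' @param n_values Bin counts to try.
#' @param k_range Cluster counts to try, each in `2..N-1`.
#' @param log_transform,normalize Passed to [bin_profile()].
#' @return `data.frame` with `n`, `k`, `mean_silhouette`, plus attributes
#'   `recommended` (list with `n`, `k`) and `degenerate` (`TRUE` when all
#'   profiles are identical and the silhouette is undefined).
#' @export
silhouette_scan <- function(profiles, n_values = 10L, k_range,
                            log_transform = TRUE, normalize = TRUE) {
  N <- length(profiles)
  stopifnot(all(k_range >= 2L), all(k_range <= N - 1L))
  out <- list()
  degenerate <- TRUE
  for (n in n_values) {
    ranges <- profile_ranges(profiles, log_transform = log_transform)
    binned <- lapply(profiles, bin_profile, n = n, ranges = ranges,
                     log_transform = log_transform, normalize = normalize)
    dmat <- profile_distance_matrix(binned)
    if (any(dmat > 0)) degenerate <- FALSE
    for (k in k_range) {
      sil <- if (all(dmat == 0)) NA_real_ else {
        pam_cluster(dmat, k)$mean_silhouette
      }
      out[[length(out) + 1L]] <- data.frame(n = as.integer(n),
                                            k = as.integer(k),
                                            mean_silhouette = sil)
    }
  }
  tab <- do.call(rbind, out)
  rec <- if (degenerate) list(n = NA_integer_, k = NA_integer_) else {
    ord <- order(-tab$mean_silhouette, tab$k, tab$n)
    list(n = tab$n[ord[1L]], k = tab$k[ord[1L]])
  }
  attr(tab, "recommended") <- rec
  attr(tab, "degenerate") <- degenerate
  if (degenerate) {
    warning("all profiles are identical; silhouette is undefined")
  }
  tab
}

#' Archetype masks: per-cluster average profiles
#'
#' Averages the normalized binned profiles of each cluster's members (each
#' profile carries the same weight), yielding one archetype mask per cluster.
#'
#' @param result A [pam_cluster()] result.
#' @param binned The list of normalized `caa_binned` profiles that `result`
#'   was computed from (same order).
#' @return List of `caa_binned` masks, one per cluster (grids sum to 1);
#'   empty clusters are skipped with a warning.
#' @export
build_masks <- function(result, binned) {
  stopifnot(inherits(result, "caa_pam"),
            length(binned) == length(result$assignments))
  if (!all(vapply(binned, `[[`, logical(1), "normalized"))) {
    stop("masks require normalized binned profiles", call. = FALSE)
  }
  lapply(seq_len(result$k), function(cl) {
    members <- which(result$assignments == cl)
    if (!length(members)) {
      warning("cluster ", cl, " is empty; skipped")
      return(NULL)
    }
    g <- Reduce(`+`, lapply(binned[members], `[[`, "grid")) / length(members)
    tmpl <- binned[[members[1L]]]
    structure(list(n = tmpl$n, grid = g, ranges = tmpl$ranges,
                   normalized = TRUE,
                   clone_id = paste0("cluster_", cl),
                   n_events = NA_integer_),
              class = "caa_binned")
  })
}

#' Count presence/absence response-profile patterns
#'
#' With each of `populations` discrete expression populations either present
#' or absent, `2^populations` phase portraits are possible (16 for the four
#' canonical quadrant populations).
#'
#' @param populations Non-negative population count.
#' @return `2^populations` as a double.
#' @export
enumerate_presence_patterns <- function(populations) {
  if (length(populations) != 1L || is.na(populations) || populations < 0 ||
      populations != floor(populations)) {
    stop("populations must be a single non-negative integer", call. = FALSE)
  }
  2^populations
}

#' Full response-profile clustering pipeline
#'
#' trim -> pooled ranges -> bin (n x n, log10, normalized) -> Manhattan
#' distances -> PAM -> archetype masks.
#'
#' @param profiles List of [response_profile()]s.
#' @param n Bins per axis (default 10, the clustering resolution).
#' @param k Number of clusters.
#' @param trim Percentile pair for [trim_outliers()]; `NULL` to skip.
#' @param log_transform Bin on the log10 scale.
#' @return List with `result` ([pam_cluster()]), `binned`, `distances`,
#'   `masks` and `assignments` (data frame clone_id, cluster, is_medoid).
#' @export
cluster_profiles <- function(profiles, n = 10L, k = 16L,
                             trim = c(0.5, 99.5), log_transform = TRUE) {
  if (!is.null(trim)) {
    profiles <- lapply(profiles, trim_outliers, lower_pct = trim[1],
                       upper_pct = trim[2])
  }
  ranges <- profile_ranges(profiles, log_transform = log_transform)
  binned <- lapply(profiles, bin_profile, n = n, ranges = ranges,
                   log_transform = log_transform, normalize = TRUE)
  dmat <- profile_distance_matrix(binned)
  result <- pam_cluster(dmat, k)
  masks <- build_masks(result, binned)
  assignments <- data.frame(
    clone_id = vapply(binned, `[[`, character(1), "clone_id"),
    cluster = result$assignments,
    is_medoid = seq_along(binned) %in% result$medoid_indices
  )
  list(result = result, binned = binned, distances = dmat, masks = masks,
       assignments = assignments)
}

#' Count local density peaks of a binned profile
#'
#' Box-smooths the grid and counts strict local maxima (8-neighbourhood)
#' rising above `min_height` times the global maximum — a simple detector for
#' the number of discrete expression populations visible in a display-
#' resolution (`n = 100`) binned profile.
#'
#' @param binned A `caa_binned` object.
#' @param smooth_radius Half-width of the box smoothing window (cells).
#' @param min_height Minimum peak height as a fraction of the smoothed
#'   maximum.
#' @return Integer peak count.
#' @export
count_density_peaks <- function(binned, smooth_radius = 2L,
                                min_height = 0.05) {
  g <- binned$grid
  n <- nrow(g)
  r <- smooth_radius
  sm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sm[i, j] <- mean(g[max(1, i - r):min(n, i + r),
                         max(1, j - r):min(n, j + r)])
    }
  }
  thr <- min_height * max(sm)
  # candidate maxima: cells not dominated by any 8-neighbour
  cand <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- sm[i, j]
      if (v < thr || v == 0) next
      nb <- sm[max(1, i - 1):min(n, i + 1), max(1, j - 1):min(n, j + 1)]
      if (v >= max(nb)) cand[[length(cand) + 1L]] <- c(i, j, v)
    }
  }
  if (!length(cand)) return(0L)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  # non-maximum suppression: plateaus and shoulders within the smoothing
  # window collapse onto the tallest cell
  min_sep <- 2L * r + 1L
  peaks <- matrix(numeric(0), ncol = 2L)
  for (q in seq_len(nrow(cand))) {
    if (nrow(peaks) == 0L ||
        all(pmax(abs(peaks[, 1] - cand[q, 1]),
                 abs(peaks[, 2] - cand[q, 2])) >= min_sep)) {
      peaks <- rbind(peaks, cand[q, 1:2])
    }
  }
  nrow(peaks)
}

#' Read per-clone event tables and manifests
#'
#' `read_clone_events()` reads one delimited text file with columns `gfp` and
#' `mcherry`; `read_manifest()` reads a manifest CSV with columns `clone_id`,
#' `variant`, `file`; `load_profiles()` combines both into a list of
#' [response_profile()]s.
#'
#' @param file Path to a clone event table.
#' @param sep Field separator (default comma).
#' @return `read_clone_events()`: data frame with `gfp`, `mcherry`.
#' @export
read_clone_events <- function(file, sep = ",") {
  ev <- utils::read.table(file, header = TRUE, sep = sep)
  if (!all(c("gfp", "mcherry") %in% names(ev))) {
    stop("event table ", file, " must have columns gfp and mcherry",
         call. = FALSE)
  }
  ev
}

#' @rdname read_clone_events
#' @param manifest Path to the manifest CSV.
#' @export
read_manifest <- function(manifest) {
  mf <- utils::read.csv(manifest)
  need <- c("clone_id", "variant", "file")
  if (!all(need %in% names(mf))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mf
}

#' @rdname read_clone_events
#' @param dir Directory the manifest's `file` column is relative to; defaults
#'   to the manifest's own directory.
#' @export
load_profiles <- function(manifest, dir = dirname(manifest)) {
  mf <- read_manifest(manifest)
  lapply(seq_len(nrow(mf)), function(i) {
    ev <- read_clone_events(file.path(dir, mf$file[i]))
    response_profile(mf$clone_id[i], ev$gfp, ev$mcherry,
                     variant = mf$variant[i])
  })
}

#' @export
print.caa_pam <- function(x, ...) {
  cat("PAM clustering: k =", x$k, ", total cost =",
      format(x$total_cost, digits = 6),
      ", mean silhouette =", format(x$mean_silhouette, digits = 4), "\n")
  cat("medoids:", x$medoid_indices, "\n")
  invisible(x)
}
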