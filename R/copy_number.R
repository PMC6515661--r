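#' A digital-PCR measurement
#'
#' Positive / total partition counts for one target assay (GFP or mCherry as
#' plasmid proxies, ALG9 as the single-copy endogenous reference).
#'
#' @param target One of `"GFP"`, `"mCherry"`, `"ALG9"`.
#' @param positive_partitions,total_partitions Counts with
#'   `0 <= positive <= total`, `total >= 1`.
#' @return Object of class `caa_dpcr`.
#' @export
dpcr_measurement <- function(target = c("GFP", "mCherry", "ALG9"),
                             positive_partitions, total_partitions) {
  target <- match.arg(target)
  stopifnot(total_partitions >= 1,
            positive_partitions >= 0,
            positive_partitions <= total_partitions)
  structure(list(target = target,
                 positive_partitions = as.integer(positive_partitions),
                 total_partitions = as.integer(total_partitions)),
            class = "caa_dpcr")
}

#' Poisson-corrected mean copies per partition
#'
#' In digital PCR the template molecules distribute over partitions as a
#' Poisson law, so the positive fraction `p` implies a mean occupancy
#' `lambda = -ln(1 - p)`.
#'
#' @param m A [dpcr_measurement()].
#' @return `lambda` (mean copies per partition). Saturated measurements
#'   (`positive == total`) are an error; all-negative measurements return 0
#'   with a warning (no quantitative information).
#' @export
lambda_from_partitions <- function(m) {
  stopifnot(inherits(m, "caa_dpcr"))
  if (m$positive_partitions == m$total_partitions) {
    stop("saturated dPCR measurement (all partitions positive): lambda is ",
         "unbounded; dilute the template", call. = FALSE)
  }
  if (m$positive_partitions == 0L) {
    warning("no positive partitions: lambda = 0 carries no information")
    return(0)
  }
  -log(1 - m$positive_partitions / m$total_partitions)
}

# variance of log(lambda-hat) by the delta method on the binomial proportion:
# d lambda / d p = 1/(1-p);  Var(p-hat) = p(1-p)/N
log_lambda_var <- function(m) {
  p <- m$positive_partitions / m$total_partitions
  lam <- -log(1 - p)
  p / ((1 - p) * m$total_partitions * lam^2)
}

#' Copy number relative to an endogenous reference
#'
#' Point estimate `reference_copies * lambda_target / lambda_reference` with a
#' delta-method confidence interval computed on the log scale (the log-ratio
#' variance is the sum of the two log-lambda variances), which keeps the
#' interval positive and gives near-nominal coverage for
#' `lambda` in roughly `[0.05, 1.5]` at usual partition counts.
#'
#' @param target_m,reference_m [dpcr_measurement()]s for the target gene and
#'   the endogenous control.
#' @param reference_copies Copies of the reference per genome (default 1: a
#'   haploid host with a single-copy control gene).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `caa_copy_number`: `target`, `copies_per_genome`,
#'   `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' tgt <- dpcr_measurement("GFP", 5100, 20000)
#' ref <- dpcr_measurement("ALG9", 1800, 20000)
#' copies_per_genome(tgt, ref)
#' @export
copies_per_genome <- function(target_m, reference_m, reference_copies = 1,
                              conf_level = 0.95) {
  stopifnot(inherits(target_m, "caa_dpcr"), inherits(reference_m, "caa_dpcr"),
            reference_copies > 0, conf_level > 0, conf_level < 1)
  if (reference_m$positive_partitions == reference_m$total_partitions ||
      reference_m$positive_partitions == 0L) {
    stop("reference measurement is saturated or empty: ratio undefined",
         call. = FALSE)
  }
  lam_t <- suppressWarnings(lambda_from_partitions(target_m))
  lam_r <- lambda_from_partitions(reference_m)
  est <- reference_copies * lam_t / lam_r
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (lam_t == 0) {
    ci <- c(0, 0)
  } else {
    se_log <- sqrt(log_lambda_var(target_m) + log_lambda_var(reference_m))
    ci <- est * exp(c(-1, 1) * z * se_log)
  }
  structure(list(target = target_m$target,
                 copies_per_genome = est,
                 ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level),
            class = "caa_copy_number")
}

#' Batch copy-number estimation from a partition-count table
#'
#' Takes a table with columns `clone_id`, `target`, `positive_partitions`,
#' `total_partitions` (one `ALG9` row per clone as the reference) and returns
#' per-clone, per-target copy-number estimates with confidence bounds.
#'
#' @param counts Data frame (or path to a CSV) of partition counts.
#' @param reference_copies Reference copies per genome (default 1).
#' @param conf_level Confidence level.
#' @return `data.frame` with `clone_id`, `target`, `copies_per_genome`,
#'   `ci_low`, `ci_high`.
#' @export
estimate_copy_numbers <- function(counts, reference_copies = 1,
                                  conf_level = 0.95) {
  if (is.character(counts)) counts <- utils::read.csv(counts)
  need <- c("clone_id", "target", "positive_partitions", "total_partitions")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (cl in unique(counts$clone_id)) {
    sub <- counts[counts$clone_id == cl, ]
    ref_row <- sub[sub$target == "ALG9", ]
    if (nrow(ref_row) != 1L) {
      stop("clone ", cl, " needs exactly one ALG9 reference row",
           call. = FALSE)
    }
    ref <- dpcr_measurement("ALG9", ref_row$positive_partitions,
                            ref_row$total_partitions)
    for (r in which(sub$target != "ALG9")) {
      tgt <- dpcr_measurement(sub$target[r], sub$positive_partitions[r],
                              sub$total_partitions[r])
      est <- copies_per_genome(tgt, ref, reference_copies, conf_level)
      out[[length(out) + 1L]] <- data.frame(
        clone_id = cl, target = est$target,
        copies_per_genome = est$copies_per_genome,
        ci_low = est$ci_low, ci_high = est$ci_high)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.caa_copy_number <- function(x, ...) {
  cat(sprintf("%s: %.3f copies/genome (%d%% CI %.3f-%.3f)\n", x$target,
              x$copies_per_genome, round(100 * x$conf_level), x$ci_low,
              x$ci_high))
  invisible(x)
}
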