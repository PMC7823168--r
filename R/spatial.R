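#' Bin tumour-adjacent clones by distance from the tumour edge
#'
#' Groups clone records into spatial bins moving away from the tumour, in
#' one of two ways. `method = "rolling"` (the default) uses overlapping bins
#' each containing exactly `bin_size` clones: records are ranked by
#' `dist_edge_cd` and successive bins advance by `stride` ranks; a final bin
#' anchored at the far end is added when needed so every record is covered
#' while the bin size stays constant. `method = "equal_width"` divides the
#' distance range into `n_bins` non-overlapping intervals of equal width,
#' which may hold different numbers of clones.
#'
#' @param records Clone-record `data.frame` with `dist_edge_cd` set
#'   (adjacent compartment).
#' @param bin_size Clones per rolling bin (default 100).
#' @param stride Rank advance between successive rolling bins (default 25).
#' @param method `"rolling"` or `"equal_width"`.
#' @param n_bins Number of bins for `method = "equal_width"`.
#' @return A list of `spatial_bin` objects, each with `bin_id`, `clone_ids`,
#'   `median_distance_cd`, and pooled per-time [clone_counts()].
#' @export
assign_rolling_bins <- function(records, bin_size = 100L, stride = 25L,
                                method = c("rolling", "equal_width"),
                                n_bins = 10L) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records))
  records <- records[!is.na(records$dist_edge_cd), , drop = FALSE]
  n <- nrow(records)
  if (n == 0L) stop("no records with a tumour-edge distance", call. = FALSE)
  ord <- order(records$dist_edge_cd)
  records <- records[ord, , drop = FALSE]
  if (method == "rolling") {
    if (bin_size > n) stop("'bin_size' exceeds the record count",
                           call. = FALSE)
    if (stride < 1L) stop("'stride' must be >= 1", call. = FALSE)
    starts <- seq.int(1L, n - bin_size + 1L, by = stride)
    if (starts[length(starts)] < n - bin_size + 1L) {
      starts <- c(starts, n - bin_size + 1L)  # cover the tail
    }
    members <- lapply(starts, function(s) s:(s + bin_size - 1L))
  } else {
    brk <- seq(min(records$dist_edge_cd), max(records$dist_edge_cd),
               length.out = n_bins + 1L)
    grp <- cut(records$dist_edge_cd, breaks = brk, include.lowest = TRUE,
               labels = FALSE)
    members <- split(seq_len(n), grp)
    members <- members[lengths(members) > 0L]
  }
  lapply(seq_along(members), function(b) {
    sub <- records[members[[b]], , drop = FALSE]
    structure(
      list(bin_id = b,
           clone_ids = sub$clone_id,
           median_distance_cd = stats::median(sub$dist_edge_cd),
           counts = as_clone_counts(sub)),
      class = "spatial_bin"
    )
  })
}

#' @export
print.spatial_bin <- function(x, ...) {
  cat(sprintf("Spatial bin %d: %d clones, median distance %.2f cd\n",
              x$bin_id, length(x$clone_ids), x$median_distance_cd))
  invisible(x)
}

#' Wild-type log-likelihood of a spatial bin
#'
#' The log-likelihood of a bin's pooled per-time clone counts under the
#' theoretical wild-type multinomial model: how well baseline neutral drift
#' describes the clones at that distance from the tumour.
#'
#' @param bin A `spatial_bin` from [assign_rolling_bins()].
#' @param wt Wild-type [drift_params()] (delay fixed at the control-data
#'   estimate).
#' @return The log-likelihood.
#' @export
bin_wt_loglik <- function(bin, wt = wt_drift_params()) {
  stopifnot(inherits(bin, "spatial_bin"))
  multinomial_loglik(bin$counts, wt)
}

#' Monte Carlo null distribution of the bin likelihood
#'
#' Simulates replicate count datasets from the theoretical wild-type
#' multinomial model, preserving the bin's per-time composition, and
#' computes each replicate's likelihood under that same model. The
#' resulting distribution calibrates how much likelihood variation finite
#' sampling alone produces in a bin of this size.
#'
#' @param composition A [clone_counts()] object (the bin's pooled counts) or
#'   named per-time totals.
#' @param wt Wild-type [drift_params()].
#' @param n_sims Number of replicates (default 1000).
#' @return A `null_distribution`: list with sorted `logliks`, `n_sims` and
#'   `quantiles` (2.5, 10, 50, 90, 97.5%).
#' @export
null_loglik_distribution <- function(composition, wt = wt_drift_params(),
                                     n_sims = 1000L) {
  sims <- simulate_wt_null_counts(wt, composition, n_sims = n_sims)
  ll <- vapply(sims, function(m) {
    multinomial_loglik(clone_counts(as.numeric(rownames(m)), m), wt)
  }, numeric(1))
  structure(
    list(logliks = ll, n_sims = n_sims,
         quantiles = stats::quantile(ll, c(0.025, 0.1, 0.5, 0.9, 0.975))),
    class = "null_distribution"
  )
}

#' Evaluate spatial bins against the wild-type null
#'
#' For each bin, computes the observed wild-type log-likelihood and its
#' Monte Carlo null distribution, and flags the bin divergent when the
#' observed value falls outside the central credible interval of the null.
#'
#' @param bins List of `spatial_bin` objects.
#' @param wt Wild-type [drift_params()].
#' @param n_sims Null replicates per bin.
#' @param level Credible level for the divergence call (0.95 or 0.8).
#' @return The bins, each augmented with `observed_loglik`,
#'   `null_quantiles` and `divergent`; the per-bin table is available via
#'   [bin_results_table()].
#' @export
evaluate_bin_divergence <- function(bins, wt = wt_drift_params(),
                                    n_sims = 1000L, level = 0.95) {
  stopifnot(level %in% c(0.8, 0.95))
  lo <- if (level == 0.95) "2.5%" else "10%"
  hi <- if (level == 0.95) "97.5%" else "90%"
  lapply(bins, function(b) {
    nd <- null_loglik_distribution(b$counts, wt, n_sims = n_sims)
    b$observed_loglik <- bin_wt_loglik(b, wt)
    b$null_quantiles <- nd$quantiles
    b$divergent <- b$observed_loglik < nd$quantiles[[lo]] ||
      b$observed_loglik > nd$quantiles[[hi]]
    b
  })
}

#' Tabulate evaluated spatial bins
#'
#' @param bins Bins returned by [evaluate_bin_divergence()].
#' @param records Optional clone records used to add the average clone size
#'   per bin.
#' @return A `data.frame` with one row per bin: median distance, observed
#'   log-likelihood, null quantiles, divergence flag and average clone size.
#' @export
bin_results_table <- function(bins, records = NULL) {
  do.call(rbind, lapply(bins, function(b) {
    avg <- NA_real_
    if (!is.null(records)) {
      avg <- mean(records$size_eighths[records$clone_id %in% b$clone_ids])
    }
    data.frame(
      bin_id = b$bin_id,
      n_clones = length(b$clone_ids),
      median_distance_cd = b$median_distance_cd,
      observed_loglik = b$observed_loglik,
      null_q025 = b$null_quantiles[["2.5%"]],
      null_q10 = b$null_quantiles[["10%"]],
      null_median = b$null_quantiles[["50%"]],
      null_q90 = b$null_quantiles[["90%"]],
      null_q975 = b$null_quantiles[["97.5%"]],
      divergent = b$divergent,
      avg_clone_size = avg
    )
  }))
}

#' Split clones by divergence from wild-type drift
#'
#' Assigns each clone record the divergence status of the spatial bins that
#' contain it: with overlapping bins, a record inherits the majority status
#' across its bins, ties resolving to divergent. Records in no bin are
#' assigned to the consistent set with a warning. The implied radial
#' distance cutoff is reported as the midpoint between the outermost
#' divergent bin's median distance and the median distance of the innermost
#' consistent bin beyond it (0 when nothing diverges, `Inf` when everything
#' does).
#'
#' @param records Clone-record `data.frame`.
#' @param bins Bins evaluated by [evaluate_bin_divergence()].
#' @return A list with `divergent` and `consistent` record subsets and
#'   `cutoff_cd`.
#' @export
split_by_divergence <- function(records, bins) {
  stopifnot(is.data.frame(records))
  if (!length(bins) || is.null(bins[[1L]]$divergent)) {
    stop("bins must first be evaluated with evaluate_bin_divergence()",
         call. = FALSE)
  }
  votes_div <- integer(nrow(records))
  votes_tot <- integer(nrow(records))
  for (b in bins) {
    idx <- records$clone_id %in% b$clone_ids
    votes_tot[idx] <- votes_tot[idx] + 1L
    if (b$divergent) votes_div[idx] <- votes_div[idx] + 1L
  }
  unbinned <- votes_tot == 0L
  if (any(unbinned)) {
    warning(sum(unbinned), " record(s) fell in no bin; ",
            "assigned to the consistent set", call. = FALSE)
  }
  is_div <- votes_tot > 0L & votes_div * 2L >= votes_tot  # ties -> divergent
  med <- vapply(bins, function(b) b$median_distance_cd, numeric(1))
  div <- vapply(bins, function(b) b$divergent, logical(1))
  if (!any(div)) {
    cutoff <- 0
  } else if (all(div)) {
    cutoff <- Inf
  } else {
    outer_div <- max(med[div])
    beyond <- med[!div & med > outer_div]
    cutoff <- if (length(beyond)) (outer_div + min(beyond)) / 2 else Inf
  }
  list(divergent = records[is_div, , drop = FALSE],
       consistent = records[!is_div, , drop = FALSE],
       cutoff_cd = cutoff)
}

#' Infer the replacement rate for a clone subset
#'
#' Rate-only Bayesian fit used for tumour-adjacent subsets: the stem-cell
#' number and the delay are fixed (at the wild-type number and the
#' control-data delay) so that the replacement rate is identifiable, and
#' only `lambda` is sampled.
#'
#' @param records Clone-record `data.frame` (non-empty).
#' @param wt_n Fixed stem-cell number (default 5).
#' @param tau Fixed delay in days (default [tau_glob()]).
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @return A list with the `summary` ([summary.posterior_draws()]) and the
#'   `draws`.
#' @export
infer_lambda_subset <- function(records, wt_n = 5L, tau = tau_glob(),
                                priors = prior_spec(),
                                config = mcmc_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty clone subset", call. = FALSE)
  counts <- as_clone_counts(records)
  if (is.null(priors$delay_max)) {
    # keep the fixed delay inside the prior support whatever the times are
    priors$delay_max <- max(tau + 1e-6, min(counts$times))
  }
  draws <- run_mcmc(counts, priors, config,
                    fixed = list(n_stem = as.integer(wt_n), delay = tau))
  list(summary = summary(draws), draws = draws)
}

#' Observed proportion of monoclonal clones
#'
#' Fraction of surviving clones that occupy the whole crypt or gland
#' (size 8/8), for a vector of scored sizes, a clone-record table, or a
#' [clone_counts()] object.
#'
#' @param x Integer sizes in 1..8, a clone-record `data.frame`, or
#'   [clone_counts()].
#' @return The monoclonal fraction in `[0, 1]`.
#' @examples
#' observed_monoclonal_proportion(c(rep(8, 69), rep(3, 204)))  # 69 of 273
#' @export
observed_monoclonal_proportion <- function(x) {
  if (inherits(x, "clone_counts")) {
    tot <- sum(x$counts)
    if (tot == 0L) stop("no surviving clones", call. = FALSE)
    return(sum(x$counts[, 8L]) / tot)
  }
  if (is.data.frame(x)) x <- x$size_eighths
  if (length(x) == 0L) stop("no surviving clones", call. = FALSE)
  if (any(x < 1 | x > 8)) stop("sizes must be in 1..8", call. = FALSE)
  mean(x == 8)
}

#' Rescale the monoclonal mass of an intra-tumour distribution
#'
#' Intra-tumour clone-size distributions carry a large monoclonal excess;
#' to compare the evolution of partial clone sizes inside and outside
#' tumours on the proportion scale, the bin-8 mass is first rescaled to the
#' external monoclonal proportion `m_ext` and the partial bins 1..7 are
#' renormalised by `(1 - m_ext) / (1 - C_8)`, preserving their relative
#' proportions.
#'
#' @param C Raw intra-tumour clone-size distribution over eighths (length 8,
#'   sums to 1, `C[8] < 1`).
#' @param m_ext Monoclonal proportion in the tumour-adjacent tissue, in
#'   `[0, 1)`.
#' @return A rescaled length-8 distribution with bin-8 mass exactly `m_ext`.
#' @export
rescale_monoclonals <- function(C, m_ext) {
  if (length(C) != 8L || any(C < 0) || abs(sum(C) - 1) > 1e-8) {
    stop("'C' must be a length-8 distribution summing to 1", call. = FALSE)
  }
  if (C[8L] >= 1 - 1e-12) {
    stop("all mass monoclonal: partial clone sizes undefined", call. = FALSE)
  }
  if (m_ext < 0 || m_ext >= 1) stop("'m_ext' must be in [0, 1)",
                                    call. = FALSE)
  out <- C * (1 - m_ext) / (1 - C[8L])
  out[8L] <- m_ext
  names(out) <- 1:8
  out
}

#' Classify intra-tumour clones as central or peripheral
#'
#' An intra-tumour clone counts as central when its distance to the tumour
#' centre is within 75% of the average tumour radius, and as edge
#' otherwise.
#'
#' @param records Intra-tumour clone records with `dist_centre_um` and
#'   `tumour_area_um2` set.
#' @param avg_radius_um Average tumour radius in microns; by default derived
#'   from the mean of the per-record disc-equivalent radii
#'   `sqrt(tumour_area_um2 / pi)`.
#' @return Character vector `"centre"`/`"edge"`, one per record.
#' @export
classify_intratumour_position <- function(records, avg_radius_um = NULL) {
  stopifnot(is.data.frame(records))
  if (any(is.na(records$dist_centre_um))) {
    stop("records lack a distance to the tumour centre", call. = FALSE)
  }
  if (is.null(avg_radius_um)) {
    if (is.null(records$tumour_area_um2) ||
        any(is.na(records$tumour_area_um2))) {
      stop("tumour geometry missing: supply 'avg_radius_um' or areas",
           call. = FALSE)
    }
    avg_radius_um <- mean(sqrt(records$tumour_area_um2 / pi))
  }
  ifelse(records$dist_centre_um < 0.75 * avg_radius_um, "centre", "edge")
}
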