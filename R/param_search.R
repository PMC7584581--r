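#' Build the synchrony reference for coupling selection
#'
#' Runs seeded simulations of the parent connectome at the reference
#' coupling and returns the mean global synchrony level (time-mean order
#' parameter averaged over samples) and the radius of its distribution (the
#' maximum absolute deviation of any sample from the mean), which is the
#' rejection threshold during surrogate coupling selection.
#'
#' @param conn the parent [connectome()].
#' @param cfg a [sim_config()] at the reference coupling `k`.
#' @param n_samples number of reference simulations (>= 2).
#' @param seeds optional integer seeds (length `n_samples`); default
#'   `cfg$seed + 0:(n_samples-1)`.
#' @return a `sync_reference`: `mean_sync`, `radius`, `sample_means`, `k`.
#' @export
build_sync_reference <- function(conn, cfg, n_samples = 8, seeds = NULL) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  if (is.null(seeds)) seeds <- cfg$seed + seq_len(n_samples) - 1
  means <- vapply(seeds, function(s) {
    c2 <- cfg; c2$seed <- s
    simulate_phases(conn, c2, record = "none")$r_mean
  }, numeric(1))
  structure(list(mean_sync = mean(means),
                 radius = max(abs(means - mean(means))),
                 sample_means = means, k = cfg$k),
            class = "sync_reference")
}

#' Select the coupling constant matching the reference synchrony
#'
#' Simulates the surrogate connectome once per value of the coupling grid
#' (fixed mean delay) and selects the `k` whose global synchrony level most
#' closely approximates the reference mean. If even the closest synchrony
#' level differs by more than the reference radius, the surrogate sample is
#' rejected (boundary values are accepted) and should be regenerated.
#'
#' @param surrogate a `surrogate_sample` or [connectome()].
#' @param ref a `sync_reference` from [build_sync_reference()].
#' @param k_grid candidate couplings (default `seq(2.5, 70, by = 2.5)`; the
#'   RSN-constrained families use `seq(50, 60, by = 2.5)`).
#' @param cfg a [sim_config()]; its `k` is overridden per grid point.
#' @param seed integer seed for the initial phases (one simulation per grid
#'   point, same seed across the grid).
#' @return list with `k` (selected, or `NA` on rejection), `rejected`,
#'   `min_diff`, `sync_by_k` (named vector).
#' @export
match_coupling <- function(surrogate, ref,
                           k_grid = seq(2.5, 70, by = 2.5), cfg,
                           seed = cfg$seed) {
  if (length(k_grid) == 0) stop("k_grid must be non-empty")
  conn <- if (inherits(surrogate, "surrogate_sample")) surrogate$connectome
          else surrogate
  sync <- vapply(k_grid, function(k) {
    c2 <- cfg; c2$k <- k; c2$seed <- seed
    simulate_phases(conn, c2, record = "none")$r_mean
  }, numeric(1))
  names(sync) <- k_grid
  diffs <- abs(sync - ref$mean_sync)
  best <- which.min(diffs)
  rejected <- diffs[best] > ref$radius
  list(k = if (rejected) NA_real_ else k_grid[best],
       rejected = rejected, min_diff = unname(diffs[best]),
       sync_by_k = sync)
}

#' Stage-one empirical fit criteria
#'
#' The first-stage screening of the two-stage empirical parameter fit:
#' a parameter set passes when the Pearson correlation between simulated and
#' reference long-time-scale FC at structurally connected edges exceeds
#' `cor_min` and the Kolmogorov-Smirnov distance between the pooled
#' time-resolved FC edge-weight distributions is below `ks_max`.
#'
#' @param sim_fc,ref_fc symmetric FC matrices (simulated, reference).
#' @param sc_mask logical matrix (or index vector) of structurally
#'   connected edges.
#' @param sim_tvfc_weights,ref_tvfc_weights pooled time-resolved FC edge
#'   weights.
#' @param cor_min,ks_max thresholds (defaults 0.33 and 0.33).
#' @return list with `pass`, `correlation`, `ks_distance`, `reason`.
#' @export
stage1_fit_criteria <- function(sim_fc, ref_fc, sc_mask,
                                sim_tvfc_weights, ref_tvfc_weights,
                                cor_min = 0.33, ks_max = 0.33) {
  x <- sim_fc[sc_mask]; y <- ref_fc[sc_mask]
  if (length(x) == 0 || length(sim_tvfc_weights) == 0 ||
      length(ref_tvfc_weights) == 0) {
    stop("empty edge mask or weight pool")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(pass = FALSE, correlation = NA_real_, ks_distance = NA_real_,
                reason = "constant FC input: correlation undefined"))
  }
  rho <- cor(x, y)
  ks <- unname(suppressWarnings(
    ks.test(sim_tvfc_weights, ref_tvfc_weights)$statistic))
  pass <- rho > cor_min && ks < ks_max
  list(pass = pass, correlation = rho, ks_distance = ks,
       reason = if (pass) "ok" else "criteria not met")
}
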