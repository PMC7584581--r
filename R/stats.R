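#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The U statistic uses midranks for ties. For
#' small samples (`length(x) + length(y) <= exact_max`) the p-value is
#' computed by exact enumeration of all group labelings (valid under ties);
#' otherwise by the normal approximation with tie-corrected variance and
#' continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max combined sample size at or below which exact enumeration
#'   is used (default 12).
#' @return list with `U` (statistic of `x`), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xv, yv) {
    r <- rank(c(xv, yv))
    sum(r[seq_along(xv)]) - length(xv) * (length(xv) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    pool <- c(x, y)
    labelings <- combn(n1 + n2, n1)
    obs <- abs(U - mu)
    us <- apply(labelings, 2, function(ix) {
      u_stat(pool[ix], pool[-ix])
    })
    p <- mean(abs(us - mu) >= obs - 1e-12)
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  r <- rank(c(x, y))
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  z <- U - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal approximation")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values across `m` comparisons, capped at one and
#' monotone non-decreasing in the sorted order.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param m number of comparisons corrected across (default
#'   `length(pvals)`).
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH", n = m)
}

#' Cliff's delta effect size
#'
#' All-pairs dominance statistic
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`, in `[-1, 1]`.
#'
#' @param x,y numeric samples (non-empty).
#' @return the delta value.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  d <- sign(outer(x, y, "-"))
  mean(d)
}

#' Compare fluctuation magnitudes between conditions
#'
#' For every pair in the comparison plan: Mann-Whitney U, two-sided raw p,
#' and Cliff's delta; p-values are then Benjamini-Hochberg adjusted across
#' all comparisons in the plan and flagged at the FDR threshold.
#'
#' @param magnitudes named list mapping condition/family name to its vector
#'   of per-sample fluctuation magnitudes (SDs).
#' @param plan list of length-2 character vectors naming the pairs to
#'   compare; default: all pairs of the supplied conditions.
#' @param alpha FDR significance level (default 0.05).
#' @return a `comparison_table` data.frame: `a`, `b`, `n_a`, `n_b`, `U`,
#'   `p`, `p_fdr`, `cliffs_delta`, `significant`.
#' @export
compare_conditions <- function(magnitudes, plan = NULL, alpha = 0.05) {
  fams <- names(magnitudes)
  if (is.null(plan)) {
    plan <- combn(fams, 2, simplify = FALSE)
  }
  for (pr in plan) {
    if (!all(pr %in% fams)) {
      stop("comparison plan names missing condition: ",
           paste(setdiff(pr, fams), collapse = ", "))
    }
  }
  rows <- lapply(plan, function(pr) {
    x <- magnitudes[[pr[1]]]; y <- magnitudes[[pr[2]]]
    mw <- mann_whitney_u(x, y)
    data.frame(a = pr[1], b = pr[2], n_a = length(x), n_b = length(y),
               U = mw$U, p = mw$p, cliffs_delta = cliffs_delta(x, y))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p, m = nrow(out))
  out$significant <- out$p_fdr < alpha
  out <- out[, c("a", "b", "n_a", "n_b", "U", "p", "p_fdr",
                 "cliffs_delta", "significant")]
  class(out) <- c("comparison_table", "data.frame")
  out
}
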