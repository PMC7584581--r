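#' Build a tapered sliding-window weight profile
#'
#' Convolves a rectangle of `width_rect` TRs with a truncated discrete
#' Gaussian kernel of standard deviation `sigma` TRs (halfwidth
#' `kernel_halfwidth`, default 3 sigma), normalized to unit sum. The taper
#' support is `width_rect + 2 * kernel_halfwidth` TRs.
#'
#' @param width_rect rectangle width in TRs (default 66; >= 2).
#' @param sigma Gaussian kernel sd in TRs (default 9; > 0).
#' @param kernel_halfwidth kernel truncation halfwidth in TRs (default
#'   `3 * sigma` rounded; 0 gives the uniform rectangle).
#' @return a `taper`: `values` (non-negative, unit sum, symmetric),
#'   `width_rect`, `sigma`, `support`.
#' @export
build_taper <- function(width_rect = 66, sigma = 9,
                        kernel_halfwidth = round(3 * sigma)) {
  if (width_rect < 2) stop("width_rect must be at least 2 TRs")
  if (sigma <= 0) stop("sigma must be positive")
  hw <- as.integer(kernel_halfwidth)
  kern <- if (hw == 0) 1 else dnorm(-hw:hw, sd = sigma)
  kern <- kern / sum(kern)
  rect <- rep(1, width_rect)
  vals <- as.numeric(convolve(rect, rev(kern), type = "open"))
  vals <- vals / sum(vals)
  structure(list(values = vals, width_rect = as.integer(width_rect),
                 sigma = sigma, support = length(vals)),
            class = "taper")
}

#' Time-resolved functional connectivity by tapered sliding windows
#'
#' For every window placement (starting at the first TR, advancing by `step`
#' TRs, keeping only fully contained windows) computes the taper-weighted
#' Pearson correlation of every node pair (the taper acts as observation
#' weights in the weighted means and covariances) and applies the Fisher
#' z-transform with `|r|` clamped at `1 - 1e-15`. Both signs are retained,
#' no thresholding is applied.
#'
#' @param bold a `bold_run` from [postprocess_bold()] (or plain matrix
#'   nodes x TRs).
#' @param taper a [build_taper()].
#' @param step window displacement in TRs (default 3).
#' @return a `tvfc_series`: `matrices` (n x n x T array of signed Fisher-z
#'   matrices with zero diagonal), `window_starts` (1-based TR indices),
#'   `step`, `taper`. The window count is
#'   `floor((n_TRs - support) / step) + 1`.
#' @export
sliding_window_fc <- function(bold, taper, step = 3) {
  series <- if (inherits(bold, "bold_run")) bold$series else as.matrix(bold)
  n <- nrow(series)
  n_tr <- ncol(series)
  sup <- taper$support
  if (n_tr < sup) stop("series shorter than the taper support")
  w <- taper$values
  starts <- seq(1, n_tr - sup + 1, by = step)
  nw <- length(starts)
  mats <- array(0, dim = c(n, n, nw))
  clamp <- 1 - 1e-15
  degenerate <- FALSE
  for (t in seq_len(nw)) {
    X <- series[, starts[t]:(starts[t] + sup - 1), drop = FALSE]
    m <- as.vector(X %*% w)
    Xc <- X - m
    cv <- (Xc * rep(w, each = n)) %*% t(Xc)
    v <- diag(cv)
    mean_sq <- as.vector((X * X) %*% w)
    zv <- v <= mean_sq * 1e-12      # zero variance up to roundoff
    if (any(zv)) { degenerate <- TRUE; v[zv] <- 1 }
    r <- cv / sqrt(outer(v, v))
    if (any(zv)) { r[zv, ] <- 0; r[, zv] <- 0 }
    r <- pmin(pmax(r, -clamp), clamp)
    z <- atanh(r)
    z <- (z + t(z)) / 2             # enforce exact symmetry
    diag(z) <- 0
    mats[, , t] <- z
  }
  if (degenerate) {
    warning("zero-variance node(s) inside a window; affected z set to 0")
  }
  structure(list(matrices = mats, window_starts = starts,
                 step = as.integer(step), taper = taper),
            class = "tvfc_series")
}
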