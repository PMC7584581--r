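#' Balloon/Windkessel hemodynamic parameters
#'
#' Standard published values for the four-state hemodynamic model: signal
#' decay `kappa`, flow feedback `gamma_f`, transit time `tau_h`, vessel
#' stiffness exponent `alpha`, resting oxygen extraction `rho`, resting
#' blood volume fraction `V0`, and a configurable scaling of the neural
#' input. Correlation-based downstream quantities are invariant to the
#' overall output scale.
#'
#' @param kappa signal decay rate, 1/s.
#' @param gamma_f flow feedback rate, 1/s.
#' @param tau_h hemodynamic transit time, s.
#' @param alpha vessel stiffness exponent, in (0, 1).
#' @param rho resting oxygen extraction fraction, in (0, 1).
#' @param V0 resting blood volume fraction.
#' @param input_gain scaling of the neural input.
#' @return a `hemo_params` list.
#' @export
hemo_params <- function(kappa = 0.65, gamma_f = 0.41, tau_h = 0.98,
                        alpha = 0.32, rho = 0.34, V0 = 0.02,
                        input_gain = 1) {
  vals <- c(kappa = kappa, gamma_f = gamma_f, tau_h = tau_h, alpha = alpha,
            rho = rho, V0 = V0, input_gain = input_gain)
  if (any(vals[c("kappa", "gamma_f", "tau_h", "V0", "input_gain")] <= 0)) {
    stop("hemodynamic rates, transit time, V0 and gain must be positive")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  structure(as.list(vals), class = "hemo_params")
}

#' Convert neural signal to raw BOLD via the Balloon/Windkessel model
#'
#' Integrates, per node independently, the four-state hemodynamic system
#' (vasodilatory signal, inflow, blood volume, deoxyhemoglobin) driven by
#' the neural amplitude, with the nonlinear BOLD observation equation, using
#' Heun integration at the input sampling step (1 ms at 1 kHz).
#'
#' @param neural a `neural_signal` from [phases_to_neural()] (or a plain
#'   nodes x time matrix at 1 kHz).
#' @param params a [hemo_params()].
#' @return a `bold_raw`: `series` (n x T), `fs` (Hz).
#' @export
balloon_windkessel <- function(neural, params = hemo_params()) {
  series <- if (inherits(neural, "neural_signal")) neural$series
            else as.matrix(neural)
  fs <- if (inherits(neural, "neural_signal")) neural$fs else 1000
  if (!all(is.finite(series))) stop("neural input must be finite")
  bold <- .balloon_windkessel(series, 1 / fs, params$kappa, params$gamma_f,
                              params$tau_h, params$alpha, params$rho,
                              params$V0, params$input_gain)
  structure(list(series = bold, fs = fs), class = "bold_raw")
}

# greedy factorization of a decimation ratio into integer stages <= 13
.decim_stages <- function(q) {
  stages <- integer(0)
  rem <- q
  for (f in c(13:2)) {
    while (rem %% f == 0 && rem > 1) {
      stages <- c(stages, f)
      rem <- rem / f
    }
  }
  if (rem != 1) stop("cannot factor decimation ratio ", q,
                     " into integer stages")
  sort(stages, decreasing = TRUE)
}

#' Post-process raw BOLD: downsample, band-pass, global-signal regression
#'
#' Anti-aliased decimation from the raw sampling rate to the TR grid
#' (integer stages with FIR anti-aliasing filters), zero-phase 2nd-order
#' Butterworth band-pass (forward-backward), and regression of the global
#' (node-mean) signal with intercept, leaving each node's series zero-mean
#' and orthogonal to the removed global regressor.
#'
#' @param raw a `bold_raw` from [balloon_windkessel()].
#' @param TR repetition time, s (default 0.72).
#' @param band band-pass corner frequencies `(low, high)` in Hz; default
#'   `c(0.021, 0.1)`. When the sliding-window width changes, set the low cut
#'   to 1 / window width.
#' @param regress_global regress out the global mean signal (default TRUE).
#' @return a `bold_run`: `series` (n x n_TRs), `TR`, `band`; `n_TRs` is
#'   exactly `floor(duration / TR)` of the input.
#' @export
postprocess_bold <- function(raw, TR = 0.72, band = c(0.021, 0.1),
                             regress_global = TRUE) {
  series <- raw$series
  fs <- raw$fs
  fs_out <- 1 / TR
  if (band[1] <= 0 || band[2] >= fs_out / 2) {
    stop("band must lie inside (0, Nyquist) at the TR sampling rate")
  }
  duration <- ncol(series) / fs
  if (duration < 3 / (2 * pi * band[1])) {
    stop("run shorter than ~3 time constants of the high-pass corner")
  }
  n_tr <- floor(duration / TR)
  q <- fs * TR
  if (abs(q - round(q)) > 1e-9) {
    stop("sampling rate must be an integer multiple of the TR rate")
  }
  stages <- .decim_stages(round(q))
  down <- t(apply(series, 1, function(x) {
    for (s in stages) x <- decimate_fir(x, s)
    x
  }))
  down <- down[, seq_len(min(n_tr, ncol(down))), drop = FALSE]

  bf <- signal::butter(2, band * 2 * TR, type = "pass")
  filt <- t(apply(down, 1, function(x) signal::filtfilt(bf, x)))

  if (regress_global) {
    g <- colMeans(filt)
    fit <- lm.fit(cbind(1, g), t(filt))
    filt <- t(fit$residuals)
  } else {
    filt <- filt - rowMeans(filt)
  }
  structure(list(series = filt, TR = TR, band = band), class = "bold_run")
}
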