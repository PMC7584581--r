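#' Simulation configuration for the delay-coupled phase model
#'
#' @param f natural oscillation frequency, Hz (default 60, gamma band).
#' @param k global coupling constant (dimensionless).
#' @param mean_delay mean interaction delay tau-bar, ms (default 12); the
#'   conduction velocity is then `v = mean(L)/tau-bar`. Supply either this
#'   or `v`, not both.
#' @param v conduction velocity, m/s (overrides `mean_delay` when given).
#' @param dt integration step, ms (default 0.2).
#' @param duration total simulated time, s (must exceed `transient`).
#' @param transient initial seconds discarded from the returned trajectory
#'   (default 20).
#' @param seed integer seed for the random initial phases.
#' @param record_hz sampling rate (Hz) of the recorded phase trajectory
#'   (default 1000; must divide the native rate `1000/dt`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(f = 60, k = 55, mean_delay = 12, v = NULL, dt = 0.2,
                       duration = 140, transient = 20, seed = 1,
                       record_hz = 1000) {
  if (dt <= 0) stop("dt must be positive")
  if (duration <= transient) stop("duration must exceed transient")
  if (!is.null(v) && !is.null(mean_delay)) mean_delay <- NULL
  if (is.null(v) && is.null(mean_delay)) {
    stop("exactly one of mean_delay and v must be set")
  }
  structure(list(f = f, k = k, mean_delay = mean_delay, v = v, dt = dt,
                 duration = duration, transient = transient, seed = seed,
                 record_hz = record_hz),
            class = "sim_config")
}

#' Normalize the structural coupling matrix
#'
#' Rescales the weight matrix so that the mean of its non-zero entries is
#' exactly one; the global coupling constant `k` then sets the overall
#' interaction strength.
#'
#' @param conn a [connectome()] (or a plain weight matrix).
#' @return the normalized coupling matrix.
#' @export
normalize_coupling <- function(conn) {
  W <- if (inherits(conn, "connectome")) conn$W else as.matrix(conn)
  nz <- W[W != 0]
  if (length(nz) == 0) stop("all-zero weight matrix cannot be normalized")
  W / mean(nz)
}

#' Simulate delay-coupled phase oscillators
#'
#' Integrates `dtheta_i/dt = 2*pi*f + k * sum_j c_ij *
#' sin(theta_j(t - tau_ij) - theta_i(t))` with the Heun predictor-corrector
#' at step `dt`, coupling `c` normalized via [normalize_coupling()], delays
#' `tau_ij = L_ij / v` rounded to the nearest integration step and realized
#' through a circular history buffer. Initial phases are uniform on
#' `[0, 2*pi)`; the initial history is the uncoupled backward rotation over
#' the maximum delay. The first `transient` seconds are discarded.
#'
#' @param conn a [connectome()].
#' @param cfg a [sim_config()].
#' @param record `"theta"` to record the phase trajectory at
#'   `cfg$record_hz`, `"none"` to keep only the order-parameter series
#'   (cheap synchrony-only runs).
#' @return a `phase_trajectory`: `theta` (n x T matrix of wrapped phases, or
#'   `NULL`), `fs` (Hz), `times` (s, absolute), `r` (order parameter per
#'   native step after the transient), `r_mean`, and the `cfg` used.
#' @export
simulate_phases <- function(conn, cfg, record = c("theta", "none")) {
  record <- match.arg(record)
  C <- normalize_coupling(conn)
  n <- nrow(C)
  L <- conn$L
  nzl <- L[upper.tri(L) & conn$W > 0]
  v <- cfg$v %||% (mean(nzl) / cfg$mean_delay)   # mm/ms == m/s
  tau <- L / v                                   # ms
  eidx <- which(C != 0, arr.ind = TRUE)          # directed edges (row <- col)
  kc <- cfg$k * C[C != 0]
  lag <- as.integer(round(tau[C != 0] / cfg$dt))
  pos_tau <- tau[C != 0]
  if (any(pos_tau > 0 & pos_tau < cfg$dt)) {
    warning("integration step dt exceeds the smallest positive delay")
  }
  native_hz <- 1000 / cfg$dt
  n_steps <- round(cfg$duration * 1000 / cfg$dt)
  n_trans <- round(cfg$transient * 1000 / cfg$dt)
  record_every <- 0L
  if (record == "theta") {
    stride <- native_hz / cfg$record_hz
    if (abs(stride - round(stride)) > 1e-9) {
      stop("record_hz must divide the native integration rate")
    }
    record_every <- as.integer(round(stride))
  }
  theta0 <- with_seed(cfg$seed, runif(n, 0, 2 * pi))
  res <- .kuramoto_heun(n, eidx[, 1] - 1L, eidx[, 2] - 1L, kc, lag, theta0,
                        cfg$dt / 1000, 2 * pi * cfg$f,
                        as.integer(n_steps), as.integer(n_trans),
                        record_every)
  theta <- if (record == "theta") res$theta else NULL
  fs <- if (record == "theta") cfg$record_hz else NA_real_
  times <- if (record == "theta") {
    cfg$transient + (seq_len(ncol(theta)) - 1) / fs
  } else NULL
  structure(list(theta = theta, fs = fs, times = times,
                 r = res$r, r_mean = res$r_mean, v = v, cfg = cfg),
            class = "phase_trajectory")
}

#' Kuramoto order parameter
#'
#' `r(t) e^{i psi(t)} = (1/N) sum_n e^{i theta_n(t)}`; `r(t)` in `[0, 1]`
#' quantifies global phase synchrony, and its time average is the global
#' synchrony level.
#'
#' @param x a `phase_trajectory` with a recorded `theta`, or a phase matrix
#'   (nodes x time).
#' @return list with `r` (per time point) and `mean`.
#' @export
order_parameter <- function(x) {
  theta <- if (inherits(x, "phase_trajectory")) x$theta else as.matrix(x)
  if (is.null(theta) || length(theta) == 0) stop("empty phase trajectory")
  z <- colMeans(exp(1i * theta))
  r <- Mod(z)
  list(r = r, mean = mean(r))
}

# anti-aliased decimation by integer factor q: zero-phase FIR low-pass
# (normalized to exact unit DC gain) followed by subsampling
decimate_fir <- function(x, q, order = 30) {
  if (q == 1) return(x)
  h <- as.numeric(signal::fir1(order, 1 / q))
  h <- h / sum(h)
  y <- signal::filtfilt(h, 1, x)
  y[seq(1, length(x), by = q)]
}

#' Transform phases to neural amplitude signal at 1 kHz
#'
#' Amplitude `sin(theta)`; trajectories recorded above 1 kHz are decimated
#' with an anti-aliasing FIR low-pass.
#'
#' @param traj a `phase_trajectory` with recorded `theta` sampled at
#'   >= 1 kHz.
#' @return a `neural_signal`: `series` (n x T in `[-1, 1]`), `fs = 1000`.
#' @export
phases_to_neural <- function(traj) {
  if (is.null(traj$theta)) stop("trajectory has no recorded phases")
  if (traj$fs < 1000) stop("trajectory must be sampled at >= 1 kHz")
  amp <- sin(traj$theta)
  if (traj$fs > 1000) {
    q <- traj$fs / 1000
    if (abs(q - round(q)) > 1e-9) {
      stop("recorded rate must be an integer multiple of 1 kHz")
    }
    amp <- t(apply(amp, 1, decimate_fir, q = round(q)))
  }
  structure(list(series = amp, fs = 1000), class = "neural_signal")
}
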