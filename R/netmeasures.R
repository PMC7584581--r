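# split a signed matrix into non-negative positive/negative parts
signed_split <- function(w) {
  list(wp = pmax(w, 0), wn = pmax(-w, 0))
}

#' Signed modularity quality function Q*
#'
#' Evaluates the generalized modularity for signed networks,
#' `Q* = (1/v+) sum_ij (w+_ij - gamma e+_ij) delta_ij -
#' (1/(v+ + v-)) sum_ij (w-_ij - gamma e-_ij) delta_ij`, with null terms
#' `e+-_ij = s+-_i s+-_j / v+-` and sums over ordered node pairs. The
#' negative term is dropped when the network has no negative weights. The
#' resolution parameter scales the null terms only.
#'
#' @param w symmetric signed weight matrix (zero diagonal).
#' @param partition community labels covering all nodes.
#' @param gamma resolution parameter (default 1).
#' @return the Q* value.
#' @export
qstar <- function(w, partition, gamma = 1) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (length(partition) != n) stop("partition must cover all nodes")
  sp <- signed_split(w)
  vp <- sum(sp$wp); vn <- sum(sp$wn)
  if (vp <= 0) stop("network has no positive weights")
  d <- outer(partition, partition, "==")
  spos <- rowSums(sp$wp)
  q <- sum((sp$wp - gamma * outer(spos, spos) / vp)[d]) / vp
  if (vn > 0) {
    sneg <- rowSums(sp$wn)
    q <- q - sum((sp$wn - gamma * outer(sneg, sneg) / vn)[d]) / (vp + vn)
  }
  q
}

#' Louvain maximization of signed modularity
#'
#' Maximizes [qstar()] with the Louvain algorithm (local moves plus
#' hierarchical aggregation) restarted `n_restarts` times with randomized
#' node visiting orders; the best partition over restarts is returned.
#'
#' @param w symmetric signed weight matrix.
#' @param gamma resolution parameter (default 1).
#' @param n_restarts number of randomized restarts (default 100).
#' @param seed integer seed controlling the restart randomization
#'   (`NULL` uses the current RNG state).
#' @return list with `membership` (integer labels, first-appearance order),
#'   `q` (maximal Q* found) and `n_communities`.
#' @export
louvain_qstar <- function(w, gamma = 1, n_restarts = 100, seed = NULL) {
  w <- as.matrix(w)
  with_seed(seed, .louvain_signed(w, gamma, as.integer(n_restarts)))
}

#' Participation coefficient over positive weights
#'
#' `PC_i = 1 - sum_c (kappa+_ic / kappa+_i)^2`, where `kappa+_ic` is node
#' i's positive strength into community `c` and `kappa+_i` its total
#' positive strength; negative weights never enter. Nodes with zero positive
#' strength get `PC = 0` with a warning.
#'
#' @param w symmetric signed weight matrix.
#' @param partition community labels.
#' @return list with `pc` (per node, in `[0, 1 - 1/N_C]`) and `mean`
#'   (over all nodes).
#' @export
participation <- function(w, partition) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (length(partition) != n) stop("partition must cover all nodes")
  wp <- pmax(w, 0)
  comms <- sort(unique(partition))
  memb <- outer(partition, comms, "==") * 1
  kic <- wp %*% memb                 # n x n_comm positive strengths
  ki <- rowSums(kic)
  zero <- ki <= 0
  if (any(zero)) {
    warning(sum(zero), " node(s) with zero positive strength; PC set to 0")
    ki[zero] <- 1
  }
  pc <- 1 - rowSums((kic / ki)^2)
  pc[zero] <- 0
  list(pc = pc, mean = mean(pc))
}

#' Temporal participation coefficient
#'
#' `TPC_{i,t} = 1 - (1/T) sum_u sum_c (kappa+_{i,c,t} / kappa+_{i,t})^2`:
#' the squared community-concentration sum of window t's positive weights is
#' averaged over all windows' community partitions `u`, improving
#' interpretability when partitions vary over time. With identical
#' partitions at every window, TPC reduces to PC.
#'
#' @param tvfc a `tvfc_series` (or n x n x T array of signed matrices).
#' @param partitions list (length T) or n x T matrix of per-window community
#'   labels.
#' @return list with `tpc` (n x T matrix) and `mean` (per window, over all
#'   nodes).
#' @export
temporal_participation <- function(tvfc, partitions) {
  mats <- if (inherits(tvfc, "tvfc_series")) tvfc$matrices else tvfc
  n <- dim(mats)[1]
  T_ <- dim(mats)[3]
  if (is.matrix(partitions)) {
    partitions <- lapply(seq_len(ncol(partitions)),
                         function(u) partitions[, u])
  }
  if (length(partitions) != T_) stop("one partition per window required")
  memb <- lapply(partitions, function(p) {
    outer(p, sort(unique(p)), "==") * 1
  })
  tpc <- matrix(0, n, T_)
  warned <- FALSE
  for (t in seq_len(T_)) {
    wp <- pmax(mats[, , t], 0)
    ki <- rowSums(wp)
    zero <- ki <= 0
    if (any(zero)) { warned <- TRUE; ki[zero] <- 1 }
    acc <- numeric(n)
    for (u in seq_len(T_)) {
      kic <- wp %*% memb[[u]]
      acc <- acc + rowSums((kic / ki)^2)
    }
    val <- 1 - acc / T_
    val[zero] <- 0
    tpc[, t] <- val
  }
  if (warned) {
    warning("node(s) with zero positive strength in a window; TPC set to 0")
  }
  list(tpc = tpc, mean = colMeans(tpc))
}

#' Per-window network measures of a time-resolved FC series
#'
#' For every window: signed-modularity Louvain ([louvain_qstar()]) gives the
#' window partition and Q*; [participation()] with that partition gives mean
#' PC; after all windows, [temporal_participation()] over the collected
#' partitions gives mean TPC. Q* tracks segregation (high = segregated),
#' mean PC and mean TPC track integration (high = integrated).
#'
#' @param tvfc a `tvfc_series`.
#' @param gamma resolution parameter (default 1).
#' @param n_restarts Louvain restarts per window (default 100).
#' @param seed integer seed for the Louvain randomization.
#' @return a `measure_series` data.frame with columns `window`, `qstar`,
#'   `mean_pc`, `mean_tpc`; the per-window partitions are attached as the
#'   `"partitions"` attribute.
#' @export
measure_series <- function(tvfc, gamma = 1, n_restarts = 100, seed = NULL) {
  mats <- tvfc$matrices
  T_ <- dim(mats)[3]
  if (T_ < 2) stop("at least two windows are required")
  qs <- numeric(T_)
  pcs <- numeric(T_)
  parts <- vector("list", T_)
  with_seed(seed, {
    for (t in seq_len(T_)) {
      lv <- louvain_qstar(mats[, , t], gamma = gamma,
                          n_restarts = n_restarts, seed = NULL)
      qs[t] <- lv$q
      parts[[t]] <- lv$membership
      pcs[t] <- participation(mats[, , t], lv$membership)$mean
    }
  })
  tpc <- temporal_participation(tvfc, parts)
  out <- data.frame(window = seq_len(T_), qstar = qs, mean_pc = pcs,
                    mean_tpc = tpc$mean)
  attr(out, "partitions") <- parts
  class(out) <- c("measure_series", "data.frame")
  out
}

#' Fluctuation magnitudes of the measure series
#'
#' The magnitude of dynamic fluctuations between segregated and integrated
#' patterns, quantified as the sample standard deviation of each global
#' measure across windows.
#'
#' @param series a `measure_series` from [measure_series()].
#' @return list with `sd_mean_pc`, `sd_mean_tpc`, `sd_qstar`.
#' @export
fluctuation_magnitude <- function(series) {
  if (nrow(series) < 2) stop("at least two windows are required")
  list(sd_mean_pc = sd(series$mean_pc),
       sd_mean_tpc = sd(series$mean_tpc),
       sd_qstar = sd(series$qstar))
}
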