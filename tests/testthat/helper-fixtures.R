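# Shared fixtures and independent oracles, built in code at test time.

# connectome of two k-cliques joined by one weak bridge edge
two_clique_connectome <- function(k = 4, w_in = 1, w_bridge = 0.05) {
  n <- 2 * k
  W <- matrix(0, n, n)
  W[1:k, 1:k] <- w_in
  W[(k + 1):n, (k + 1):n] <- w_in
  diag(W) <- 0
  W[k, k + 1] <- W[k + 1, k] <- w_bridge
  L <- ifelse(W > 0, 10, 0)
  nodes <- data.frame(node_id = 0:(n - 1), x = seq_len(n), y = 0, z = 0,
                      structural_community = rep(1:2, each = k),
                      rsn = NA_character_)
  connectome(W, L, nodes)
}

# small connected weighted graph with distinct edge lengths
path_connectome <- function(n = 5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- i
  L <- ifelse(W > 0, 5 * (W + 1), 0)
  nodes <- data.frame(node_id = 0:(n - 1), x = seq_len(n), y = 0, z = 0,
                      structural_community = 1L, rsn = NA_character_)
  connectome(W, L, nodes)
}

# enumerate all set partitions of 1..n as label vectors (restricted growth)
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(labels, used) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (c in seq_len(used + 1)) rec(c(labels, c), max(used, c))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum of the signed modularity over all partitions
exhaustive_qstar <- function(w, gamma = 1) {
  parts <- enumerate_partitions(nrow(w))
  qs <- vapply(parts, function(p) qstar(w, p, gamma = gamma), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# literal direct-summation evaluation of the signed modularity (independent
# of the package's vectorized implementation)
direct_qstar <- function(w, partition, gamma = 1) {
  n <- nrow(w)
  wp <- matrix(0, n, n); wn <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (w[i, j] > 0) wp[i, j] <- w[i, j] else wn[i, j] <- -w[i, j]
  }
  vp <- sum(wp); vn <- sum(wn)
  sp <- rowSums(wp); sn <- rowSums(wn)
  q <- 0
  for (i in 1:n) for (j in 1:n) {
    if (partition[i] == partition[j]) {
      q <- q + (wp[i, j] - gamma * sp[i] * sp[j] / vp) / vp
      if (vn > 0) {
        q <- q - (wn[i, j] - gamma * sn[i] * sn[j] / vn) / (vp + vn)
      }
    }
  }
  q
}

# random signed symmetric matrix with zero diagonal
random_signed_network <- function(n, seed) {
  set.seed(seed)
  w <- matrix(rnorm(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# weighted rich-club curve computed by an explicit loop (test oracle)
direct_richclub_curve <- function(W) {
  deg <- rowSums(W > 0)
  total <- sum(W) / 2
  vapply(seq_len(max(deg) - 1), function(d) {
    keep <- which(deg > d)
    if (length(keep) < 2) return(NA_real_)
    s <- 0
    for (a in keep) for (b in keep) if (a < b) s <- s + W[a, b]
    s / total
  }, numeric(1))
}

# adjusted Rand index between two labelings (independent small helper)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- si * sj / comb2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# small desk config for fast pipeline smoke runs
smoke_config <- function() {
  cfg <- default_config(n_nodes = 24, n_samples = 2, duration = 50)
  cfg$sim$transient <- 10
  cfg$search$k_grid <- c(10, 55)
  cfg$search$sync_duration <- 5
  cfg$search$sync_transient <- 5
  cfg$search$n_reference <- 2
  cfg$tvfc$width_rect <- 20
  cfg$tvfc$sigma <- 3
  cfg$tvfc$band <- c(1 / (20 * 0.72), 0.12)
  cfg$measures$n_restarts <- 20
  cfg$surrogates$families <- c("R", "G")
  cfg$surrogates$n_bins <- 5
  cfg$search$radius <- Inf
  cfg
}
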