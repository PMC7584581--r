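test_that("signed modularity matches the direct-summation oracle", {
  conn <- two_clique_connectome()
  p <- rep(1:2, each = 4)
  expect_equal(qstar(conn$W, p), direct_qstar(conn$W, p), tolerance = 1e-12)

  # single-community partition is exactly zero (null totals match totals)
  for (s in 1:5) {
    w <- random_signed_network(7, s)
    expect_equal(qstar(w, rep(1, 7)), 0, tolerance = 1e-12)
    p2 <- sample(1:3, 7, replace = TRUE)
    expect_equal(qstar(w, p2), direct_qstar(w, p2), tolerance = 1e-12)
    expect_equal(qstar(w, p2, gamma = 1.4),
                 direct_qstar(w, p2, gamma = 1.4), tolerance = 1e-12)
  }

  # sign flip exchanges the roles of the two terms
  w <- random_signed_network(6, 9)
  p <- c(1, 1, 2, 2, 3, 3)
  sp <- pmax(w, 0); sn <- pmax(-w, 0)
  vp <- sum(sp); vn <- sum(sn)
  d <- outer(p, p, "==")
  term <- function(m) {
    s <- rowSums(m)
    sum((m - outer(s, s) / sum(m))[d])
  }
  q_flip <- term(sn) / vn - term(sp) / (vp + vn)
  expect_equal(qstar(-w, p), q_flip, tolerance = 1e-12)

  expect_error(qstar(-abs(random_signed_network(4, 1)), rep(1, 4)),
               "positive")
  expect_error(qstar(w, 1:3), "cover all nodes")
})

test_that("Louvain attains the exhaustive optimum on small signed
           networks", {
  # random signed fixtures, n <= 8
  for (s in 1:6) {
    n <- 5 + (s %% 4)
    w <- random_signed_network(n, s)
    ex <- exhaustive_qstar(w)
    lv <- louvain_qstar(w, n_restarts = 100, seed = s)
    expect_gte(lv$q, ex$q - 1e-9)
    expect_equal(qstar(w, lv$membership), lv$q, tolerance = 1e-12)
  }

  # two anti-correlated blocks: positive within, negative between
  w <- matrix(-0.5, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  lv <- louvain_qstar(w, seed = 1)
  expect_equal(adjusted_rand(lv$membership, rep(1:2, each = 4)), 1)

  # resolution parameter only scales the null terms
  w2 <- random_signed_network(7, 3)
  p <- c(1, 2, 1, 2, 3, 3, 1)
  expect_equal(qstar(w2, p, gamma = 2) - qstar(w2, p, gamma = 0),
               -(qstar(w2, p, gamma = 0) - qstar(w2, p, gamma = 1)) * 2,
               tolerance = 1e-12)

  # determinism under a fixed seed
  w3 <- random_signed_network(8, 4)
  expect_identical(louvain_qstar(w3, seed = 7)$membership,
                   louvain_qstar(w3, seed = 7)$membership)
})

test_that("participation coefficient matches analytic cases", {
  # node 1 fully inside community 1
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  p <- c(1, 1, 2, 2)
  w[3, 4] <- w[4, 3] <- 1
  res <- participation(w, p)
  expect_equal(res$pc[1], 0)

  # equal strength to two communities
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 1
  w2[1, 3] <- w2[3, 1] <- 1
  expect_equal(participation(w2, c(1, 1, 2))$pc[1], 0.5)

  # strengths (3, 1) across two communities: 1 - (9 + 1)/16
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 3
  w3[1, 3] <- w3[3, 1] <- 1
  expect_equal(participation(w3, c(1, 1, 2))$pc[1], 0.375)

  # negative weights never enter; zero positive strength warns
  w4 <- w3; w4[1, 2] <- w4[2, 1] <- -3
  expect_equal(suppressWarnings(participation(w4, c(1, 1, 2)))$pc[1], 0)
  w5 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_warning(r5 <- participation(w5, c(1, 2)), "zero positive")
  expect_equal(r5$pc, c(0, 0))

  # bounds: PC in [0, 1 - 1/N_C]
  set.seed(8)
  for (i in 1:10) {
    w6 <- abs(random_signed_network(9, i))
    p6 <- sample(1:3, 9, replace = TRUE)
    pc <- participation(w6, p6)$pc
    expect_true(all(pc >= 0 & pc <= 1 - 1 / length(unique(p6)) + 1e-12))
  }
})

test_that("temporal participation matches its brute-force definition", {
  set.seed(21)
  n <- 6; T_ <- 4
  mats <- array(rnorm(n * n * T_), c(n, n, T_))
  for (t in 1:T_) {
    mats[, , t] <- (mats[, , t] + t(mats[, , t])) / 2
    diag(mats[, , t]) <- 0
  }
  parts <- lapply(1:T_, function(t) sample(1:3, n, replace = TRUE))
  res <- temporal_participation(mats, parts)

  # independent double-loop oracle
  oracle <- matrix(0, n, T_)
  for (t in 1:T_) {
    wp <- pmax(mats[, , t], 0)
    for (i in 1:n) {
      ki <- sum(wp[i, ])
      acc <- 0
      for (u in 1:T_) {
        for (c in unique(parts[[u]])) {
          kic <- sum(wp[i, parts[[u]] == c])
          acc <- acc + (kic / ki)^2
        }
      }
      oracle[i, t] <- 1 - acc / T_
    }
  }
  expect_equal(res$tpc, oracle, tolerance = 1e-12)

  # identical partitions at every window: TPC == PC, window by window
  same <- lapply(1:T_, function(t) parts[[1]])
  res2 <- temporal_participation(mats, same)
  for (t in 1:T_) {
    expect_equal(res2$tpc[, t], participation(mats[, , t], parts[[1]])$pc,
                 tolerance = 1e-12)
  }

  # single window: TPC == PC
  one <- array(mats[, , 1], c(n, n, 1))
  res3 <- temporal_participation(one, parts[1])
  expect_equal(res3$tpc[, 1], participation(mats[, , 1], parts[[1]])$pc,
               tolerance = 1e-12)
})

test_that("measure series tracks segregation/integration and their SDs", {
  n <- 10
  seg <- matrix(-0.4, n, n)           # two blocks: segregated pattern
  seg[1:5, 1:5] <- 0.8
  seg[6:10, 6:10] <- 0.8
  diag(seg) <- 0
  int <- matrix(0.6, n, n)            # strong between-block coupling:
  int[1:5, 1:5] <- 0.8                # integrated two-community pattern
  int[6:10, 6:10] <- 0.8
  diag(int) <- 0
  T_ <- 6
  mats <- array(0, c(n, n, T_))
  for (t in 1:T_) mats[, , t] <- if (t %% 2 == 1) seg else int
  fc <- structure(list(matrices = mats, window_starts = seq_len(T_),
                       step = 1L), class = "tvfc_series")
  ms <- measure_series(fc, n_restarts = 25, seed = 3)
  expect_equal(nrow(ms), T_)
  seg_idx <- seq(1, T_, by = 2); int_idx <- seq(2, T_, by = 2)
  # segregated windows: high modularity, low mean PC
  expect_gt(min(ms$qstar[seg_idx]), max(ms$qstar[int_idx]))
  expect_lt(max(ms$mean_pc[seg_idx]), min(ms$mean_pc[int_idx]))

  # frozen FC: all three series constant, SDs exactly zero
  frozen <- array(rep(seg, T_), c(n, n, T_))
  fcf <- structure(list(matrices = frozen, window_starts = seq_len(T_),
                        step = 1L), class = "tvfc_series")
  msf <- measure_series(fcf, n_restarts = 25, seed = 5)
  mag <- fluctuation_magnitude(msf)
  expect_equal(mag$sd_mean_pc, 0)
  expect_equal(mag$sd_qstar, 0)
  expect_equal(mag$sd_mean_tpc, 0)
})

test_that("fluctuation magnitude is the sample SD with its equivariance", {
  ms <- data.frame(window = 1:2, qstar = c(0, 1), mean_pc = c(0, 1),
                   mean_tpc = c(0.3, 0.3))
  mag <- fluctuation_magnitude(ms)
  expect_equal(mag$sd_mean_pc, sqrt(0.5))
  expect_equal(mag$sd_qstar, sqrt(0.5))
  expect_equal(mag$sd_mean_tpc, 0)
  # scale equivariance
  ms2 <- ms; ms2$mean_pc <- ms$mean_pc * -3.5
  expect_equal(fluctuation_magnitude(ms2)$sd_mean_pc, 3.5 * sqrt(0.5))
  expect_error(fluctuation_magnitude(ms[1, ]), "two windows")
})
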