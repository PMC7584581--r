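test_that("structural community detection recovers planted structure", {
  conn <- two_clique_connectome()
  part <- detect_structural_communities(conn, seed = 1)
  expect_equal(adjusted_rand(part, rep(1:2, each = 4)), 1)
  # agrees with the exhaustive optimum on this 8-node graph
  ex <- exhaustive_qstar(conn$W)
  expect_equal(qstar(conn$W, part), ex$q, tolerance = 1e-12)

  # complete uniform graph: no partition beats the all-in-one partition
  n <- 6
  W <- matrix(1, n, n); diag(W) <- 0
  L <- ifelse(W > 0, 10, 0)
  cu <- connectome(W, L, data.frame(node_id = 0:(n - 1), x = 1:n, y = 0,
                                    z = 0, structural_community = 1L,
                                    rsn = NA))
  p2 <- detect_structural_communities(cu, seed = 1)
  expect_lte(qstar(cu$W, p2), qstar(cu$W, rep(1, n)) + 1e-12)

  # planted four-community synthetic connectome at strong multipliers
  nodes <- generate_geometry(48, seed = 3)
  strong <- generate_connectome(nodes, seed = 3, community_boost = 12,
                                hub_boost = 1, noise_sdlog = 0.2)
  rec <- detect_structural_communities(strong, seed = 2)
  expect_equal(adjusted_rand(rec, strong$nodes$structural_community), 1)

  empty <- two_clique_connectome()
  empty$W[] <- 0
  expect_error(detect_structural_communities(empty), "empty")
})

test_that("length-bin selection follows the descending scan contract", {
  # dense length pool: expected occupancy ~50 per bin at 100 bins
  set.seed(42)
  n <- 101
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  picked <- sample(ut, 5000)
  W[picked] <- runif(5000, 0.5, 1)
  W <- W + t(W)
  L <- ifelse(W > 0, matrix(runif(n * n, 10, 150), n, n), 0)
  L[lower.tri(L)] <- t(L)[lower.tri(L)]
  L <- ifelse(W > 0, (L + t(L)) / 2, 0)
  fake <- list(W = W, L = L)
  spec <- select_length_bins(fake)
  expect_equal(spec$n_bins, 100L)
  # direct verification of both criteria at the returned count
  lens <- L[upper.tri(L) & W > 0]
  br <- seq(min(lens), max(lens), length.out = 101)
  counts <- tabulate(pmin(findInterval(lens, br, left.open = FALSE), 100),
                     nbins = 100)
  expect_lte(mean(counts <= 3), 0.1)
  expect_true(all(counts > 1))
  expect_equal(sort(spec$counts), sort(counts))

  # all-identical lengths: both criteria can never hold together
  p <- path_connectome(13)  # 12 edges
  p$L[p$L > 0] <- 25
  expect_error(select_length_bins(p), "more than one edge")

  # forced override builds exactly that many equal-width bins
  conn <- synthetic_connectome(57, seed = 1)
  forced <- select_length_bins(conn, n_bins = 30)
  expect_equal(forced$n_bins, 30L)
  expect_equal(length(forced$boundaries), 31L)
  expect_true(all(abs(diff(diff(forced$boundaries))) < 1e-9))
})

test_that("rich-club categories follow min-degree and preserve the curve", {
  # star K_{1,4}: every edge touches a leaf of degree 1
  n <- 5
  W <- matrix(0, n, n); W[1, 2:5] <- 1; W <- W + t(W)
  L <- ifelse(W > 0, 10, 0)
  star <- connectome(W, L, data.frame(node_id = 0:4, x = 1:5, y = 0, z = 0,
                                      structural_community = 1L, rsn = NA))
  expect_true(all(richclub_categories(star) == 1))

  W2 <- matrix(0, 3, 3); W2[upper.tri(W2)] <- c(1, 2, 3); W2 <- W2 + t(W2)
  tri <- connectome(W2, ifelse(W2 > 0, 5, 0),
                    data.frame(node_id = 0:2, x = 1:3, y = 0, z = 0,
                               structural_community = 1L, rsn = NA))
  expect_true(all(richclub_categories(tri) == 2))

  # permuting within categories leaves the weighted rich-club curve intact
  conn <- synthetic_connectome(50, seed = 6)
  cells <- build_cells(conn, "T", partition = rep(1L, 50))  # category-only
  smp <- permute_within_cells(conn, cells, seed = 3)
  expect_false(identical(smp$connectome$W, conn$W))
  expect_equal(direct_richclub_curve(smp$connectome$W),
               direct_richclub_curve(conn$W), tolerance = 1e-12)
})

test_that("cell construction matches each family's constraint", {
  conn <- synthetic_connectome(57, seed = 1)
  part <- detect_structural_communities(conn, seed = 4)
  bins <- select_length_bins(conn)

  r <- build_cells(conn, "R")
  expect_equal(r$permutable_fraction, 1.0)
  expect_equal(length(r$cells), 1L)

  g <- build_cells(conn, "G", bins = bins)
  t_ <- build_cells(conn, "T", partition = part)
  gt <- build_cells(conn, "GT", bins = bins, partition = part)
  # every family partitions the full edge set
  for (cp in list(r, g, t_, gt)) {
    expect_equal(sort(unlist(cp$cells)), seq_len(cp$n_edges))
  }
  # refinement never increases the permutable pool
  expect_gte(r$permutable_fraction, g$permutable_fraction)
  expect_gte(g$permutable_fraction, gt$permutable_fraction)
  expect_gte(r$permutable_fraction, t_$permutable_fraction)
  expect_gte(t_$permutable_fraction, gt$permutable_fraction)

  # all-singleton cells mean nothing is permutable
  p5 <- path_connectome(5)
  fine <- select_length_bins(p5, n_bins = 50)
  gt0 <- build_cells(p5, "GT", bins = fine, partition = c(1L, 1L, 2L, 2L, 3L))
  expect_equal(gt0$permutable_fraction, 0)

  expect_error(build_cells(conn, "G"), "requires length bins")
  expect_error(build_cells(conn, "GT", bins = bins, partition = 1:10),
               "cover all nodes")
  expect_error(build_cells(path_connectome(6), "G", bins = bins),
               "does not match")
})

test_that("within-cell permutation conserves multisets, support and bins", {
  conn <- synthetic_connectome(57, seed = 2)
  bins <- select_length_bins(conn)
  part <- detect_structural_communities(conn, seed = 4)

  # singleton cell leaves W identical
  p5 <- path_connectome(5)
  fine <- select_length_bins(p5, n_bins = 50)
  gt0 <- build_cells(p5, "GT", bins = fine, partition = c(1L, 1L, 2L, 2L, 3L))
  expect_identical(permute_within_cells(p5, gt0, seed = 1)$connectome$W,
                   p5$W)

  for (fam in c("R", "G", "T", "GT")) {
    cells <- build_cells(conn, fam, bins = bins, partition = part)
    smp <- permute_within_cells(conn, cells, seed = 9)
    W2 <- smp$connectome$W
    # support and lengths identical
    expect_identical(W2 > 0, conn$W > 0)
    expect_identical(smp$connectome$L, conn$L)
    # global multiset identical
    expect_equal(sort(W2[upper.tri(W2)]), sort(conn$W[upper.tri(conn$W)]))
    # per-cell multisets identical
    eidx <- cells$edge_idx
    for (cell in cells$cells) {
      expect_equal(sort(W2[eidx[cell]]), sort(conn$W[eidx[cell]]))
    }
    # determinism and seed sensitivity
    expect_identical(permute_within_cells(conn, cells, seed = 9)$connectome$W,
                     W2)
    if (cells$permutable_fraction > 0) {
      expect_false(identical(
        permute_within_cells(conn, cells, seed = 10)$connectome$W, W2))
    }
  }

  # G preserves per-bin mean weights exactly pre-adjustment
  gcells <- build_cells(conn, "G", bins = bins)
  smp <- permute_within_cells(conn, gcells, seed = 5)
  eidx <- gcells$edge_idx
  m1 <- tapply(conn$W[eidx], bins$bin_of_edge, mean)
  m2 <- tapply(smp$connectome$W[eidx], bins$bin_of_edge, mean)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("strength adjustment restores the parent strength sequence", {
  conn <- synthetic_connectome(57, seed = 3)
  target <- rowSums(conn$W)

  # identity permutation is a fixed point
  ident <- adjust_strength_sequence(conn, target_strengths = target)
  expect_equal(ident$connectome$W, conn$W, tolerance = 1e-12)
  expect_equal(ident$iterations, 0L)

  cells <- build_cells(conn, "R")
  smp <- permute_within_cells(conn, cells, seed = 7)
  adj <- adjust_strength_sequence(smp, target_strengths = target)
  achieved <- rowSums(adj$connectome$W)
  expect_gt(cor(target, achieved), 0.999)
  expect_lt(adj$strength_error, 1e-3)
  # support and positivity survive the correction
  expect_identical(adj$connectome$W > 0, conn$W > 0)
  expect_true(all(adj$connectome$W[conn$W > 0] > 0))

  # geometry family: the weight-length profile survives the adjustment
  bins <- select_length_bins(conn)
  gsmp <- make_surrogate(conn, build_cells(conn, "G", bins = bins), seed = 5)
  eidx <- edge_index(conn$W)
  m_par <- tapply(conn$W[eidx], bins$bin_of_edge, mean)
  m_adj <- tapply(gsmp$connectome$W[eidx], bins$bin_of_edge, mean)
  expect_gt(cor(m_par, m_adj), 0.7)
  expect_lt(cor(gsmp$connectome$W[eidx], conn$L[eidx], method = "spearman"),
            -0.15)

  expect_error(adjust_strength_sequence(conn, target_strengths = 0 * target),
               "positive")
})

test_that("GT surrogates preserve block sums and the rich-club curve", {
  conn <- synthetic_connectome(57, seed = 4)
  part <- detect_structural_communities(conn, seed = 4)
  bins <- select_length_bins(conn)
  gt <- build_cells(conn, "GT", bins = bins, partition = part)
  smp <- permute_within_cells(conn, gt, seed = 11)
  W2 <- smp$connectome$W

  # per-community-block weight sums exact
  eidx <- gt$edge_idx
  ij <- arrayInd(eidx, dim(conn$W))
  block <- ifelse(part[ij[, 1]] == part[ij[, 2]],
                  paste0("c", part[ij[, 1]]), "between")
  expect_equal(tapply(W2[eidx], block, sum),
               tapply(conn$W[eidx], block, sum), tolerance = 1e-12)
  # weighted rich-club curve exact
  expect_equal(direct_richclub_curve(W2), direct_richclub_curve(conn$W),
               tolerance = 1e-12)
})

test_that("RSN main/control pairs freeze the right edges and equalize", {
  conn <- synthetic_connectome(57, seed = 5)
  part <- detect_structural_communities(conn, seed = 4)
  bins <- select_length_bins(conn)
  gt <- build_cells(conn, "GT", bins = bins, partition = part)

  pair <- make_rsn_pair(conn, gt, "VIS", seed = 1)
  eidx <- gt$edge_idx
  ij <- arrayInd(eidx, dim(conn$W))
  vis_nodes <- which(as.character(conn$nodes$rsn) == "VIS")
  incident <- ij[, 1] %in% vis_nodes | ij[, 2] %in% vis_nodes
  # main permutable edges are all incident; control's never are
  main_pool <- unlist(pair$main$cells[lengths(pair$main$cells) >= 2])
  ctrl_pool <- unlist(pair$control$cells[lengths(pair$control$cells) >= 2])
  expect_true(all(incident[main_pool]))
  expect_true(all(!incident[ctrl_pool]))
  expect_lt(abs(pair$fraction_main - pair$fraction_control), 2 / gt$n_edges)

  # permuting main cells only changes incident edges
  smp <- permute_within_cells(conn, pair$main, seed = 2)
  changed <- which(smp$connectome$W[eidx] != conn$W[eidx])
  expect_true(all(incident[changed]))

  # an RSN covering every node leaves an empty control pool
  all_vis <- conn
  all_vis$nodes$rsn <- factor(rep("VIS", nrow(all_vis$nodes)),
                              levels = rsn_levels)
  expect_error(make_rsn_pair(all_vis, gt, "VIS", seed = 1), "empty")

  # disjoint RSNs: shared permutable edges connect the two RSNs
  pair_b <- make_rsn_pair(conn, gt, "DMN", seed = 1)
  pool_b <- unlist(pair_b$main$cells[lengths(pair_b$main$cells) >= 2])
  dmn_nodes <- which(as.character(conn$nodes$rsn) == "DMN")
  shared <- intersect(main_pool, pool_b)
  touches_both <- (ij[, 1] %in% vis_nodes | ij[, 2] %in% vis_nodes) &
    (ij[, 1] %in% dmn_nodes | ij[, 2] %in% dmn_nodes)
  expect_setequal(shared, intersect(which(touches_both),
                                    intersect(main_pool, pool_b)))
  expect_true(all(touches_both[shared]))
})
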