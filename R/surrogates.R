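#' Detect structural communities by signed-modularity maximization
#'
#' Runs the Louvain maximization of the signed modularity quality function on
#' the (non-negative) structural weight matrix; with no negative weights the
#' negative-null term drops out. The best partition over `n_restarts`
#' randomized restarts is returned and is the community structure frozen into
#' the topology-constrained surrogate families.
#'
#' @param conn a [connectome()].
#' @param gamma resolution parameter of the null terms (default 1).
#' @param n_restarts Louvain restarts with randomized node visiting order
#'   (default 100).
#' @param seed integer seed controlling the restart randomization.
#' @return integer community labels (length n).
#' @export
detect_structural_communities <- function(conn, gamma = 1, n_restarts = 100,
                                          seed = NULL) {
  if (all(conn$W == 0)) stop("empty graph: no edges to cluster")
  louvain_qstar(conn$W, gamma = gamma, n_restarts = n_restarts,
                seed = seed)$membership
}

# bin assignment for edge lengths over nb equal-width bins spanning [lo, hi];
# half-open [lo, hi) intervals, last bin closed
.bin_assign <- function(lens, lo, hi, nb) {
  if (hi <= lo) return(rep(1L, length(lens)))
  width <- (hi - lo) / nb
  pmin.int(floor((lens - lo) / width) + 1L, nb)
}

#' Select the number of equal-width length bins
#'
#' Scans candidate bin counts 100, 90, ..., 10 (descending) and accepts the
#' first count at which the percentage of bins containing three or fewer
#' edges is at most `sparse_max_frac` and every bin contains more than one
#' edge. Bins are equal-width over the range of streamline lengths of the
#' non-zero edges.
#'
#' @param conn a [connectome()] with at least one edge.
#' @param candidates descending candidate bin counts.
#' @param sparse_max_frac maximal tolerated fraction of sparse bins
#'   (<= `sparse_edges` edges), default 0.1.
#' @param sparse_edges occupancy at or below which a bin counts as sparse.
#' @param n_bins optional override: build the bin specification at exactly
#'   this count without scanning (the selection criteria are then reported
#'   but not enforced).
#' @return a `bin_spec` object: `n_bins`, `boundaries` (mm), `bin_of_edge`
#'   (per non-zero upper-triangle edge), `counts`, `sparse_frac`.
#' @export
select_length_bins <- function(conn, candidates = seq(100L, 10L, by = -10L),
                               sparse_max_frac = 0.1, sparse_edges = 3L,
                               n_bins = NULL) {
  eidx <- edge_index(conn$W)
  if (length(eidx) < 1) stop("connectome has no edges")
  lens <- conn$L[eidx]
  lo <- min(lens); hi <- max(lens)
  build <- function(nb) {
    b <- .bin_assign(lens, lo, hi, nb)
    counts <- tabulate(b, nbins = nb)
    structure(list(n_bins = as.integer(nb),
                   boundaries = seq(lo, hi, length.out = nb + 1),
                   bin_of_edge = b, counts = counts,
                   n_edges = length(eidx),
                   sparse_frac = mean(counts <= sparse_edges)),
              class = "bin_spec")
  }
  if (!is.null(n_bins)) return(build(n_bins))
  for (nb in candidates) {
    spec <- build(nb)
    if (spec$sparse_frac <= sparse_max_frac && all(spec$counts > 1)) {
      return(spec)
    }
  }
  stop(paste0("no candidate bin count satisfied both criteria: ",
              "sparse-bin percentage <= ", 100 * sparse_max_frac,
              "% and all bins containing more than one edge"))
}

#' Rich-club edge categories
#'
#' Assigns every non-zero edge the category `d = min(degree_i, degree_j)`
#' with degrees computed on the binarized graph. Permuting weights within
#' categories leaves the weighted rich-club curve unchanged, because the
#' edges among nodes of degree greater than `d` are exactly those in
#' categories above `d`.
#'
#' @param conn a [connectome()].
#' @return integer category per non-zero upper-triangle edge.
#' @export
richclub_categories <- function(conn) {
  deg <- rowSums(conn$W > 0)
  eidx <- edge_index(conn$W)
  ij <- arrayInd(eidx, dim(conn$W))
  as.integer(pmin(deg[ij[, 1]], deg[ij[, 2]]))
}

#' Weighted rich-club coefficient curve
#'
#' For each degree threshold `d`, the ratio of the sum of weights of edges
#' between nodes of degree greater than `d` to the total weight sum. With
#' `normalize = TRUE` the raw curve is divided by its mean over unconstrained
#' weight permutations on the same support, the form in which a weighted rich
#' club appears as an increasing curve over the top degree range.
#'
#' @param conn a [connectome()].
#' @param d_values degree thresholds (default 1 to max degree - 1).
#' @param normalize divide by the permutation-null mean curve.
#' @param n_null number of weight permutations for the null (normalize only).
#' @param seed seed for the null permutations.
#' @return data.frame with `d`, `phi` (and `phi_norm` if normalized).
#' @export
rich_club_w <- function(conn, d_values = NULL, normalize = FALSE,
                        n_null = 50, seed = 1) {
  W <- conn$W
  deg <- rowSums(W > 0)
  if (is.null(d_values)) d_values <- seq_len(max(deg) - 1)
  total <- sum(W) / 2
  curve <- function(M) {
    vapply(d_values, function(d) {
      keep <- deg > d
      if (sum(keep) < 2) return(NA_real_)
      sum(M[keep, keep]) / 2 / total
    }, numeric(1))
  }
  phi <- curve(W)
  out <- data.frame(d = d_values, phi = phi)
  if (normalize) {
    eidx <- edge_index(W)
    acc <- numeric(length(d_values))
    with_seed(seed, {
      for (b in seq_len(n_null)) {
        Wp <- W * 0
        Wp[eidx] <- W[eidx][sample.int(length(eidx))]
        Wp <- Wp + t(Wp)
        acc <- acc + curve(Wp)
      }
    })
    out$phi_norm <- phi / (acc / n_null)
  }
  out
}

# internal: build a cell_partition from a per-edge key vector
.cells_from_key <- function(conn, key, tags, family) {
  eidx <- edge_index(conn$W)
  cells <- split(seq_along(eidx), key)
  sizes <- lengths(cells)
  structure(list(cells = unname(cells),
                 constraint_tags = tags,
                 family = family,
                 edge_idx = eidx,
                 n_nodes = nrow(conn$W),
                 n_edges = length(eidx),
                 permutable_fraction = sum(sizes[sizes >= 2]) / length(eidx)),
            class = "cell_partition")
}

#' Build the permutation-cell partition for a surrogate family
#'
#' Partitions the non-zero edge set into disjoint cells within which weights
#' may be permuted: family `R` puts every edge in one cell (no constraint);
#' `G` one cell per equal-width length bin (geometry); `T` cells are the
#' intersection of the community block (within community c, or the single
#' between-communities block) with the rich-club degree category (topology);
#' `GT` intersects all three.
#'
#' @param conn parent [connectome()].
#' @param family one of `"R"`, `"G"`, `"T"`, `"GT"`.
#' @param bins a `bin_spec` from [select_length_bins()] (required for G, GT).
#' @param partition community labels from
#'   [detect_structural_communities()] (required for T, GT).
#' @return a `cell_partition`: disjoint cells covering all non-zero edges,
#'   constraint tags, and `permutable_fraction` (fraction of edges lying in
#'   cells of size >= 2, i.e. the permutation pool).
#' @export
build_cells <- function(conn, family = c("R", "G", "T", "GT"),
                        bins = NULL, partition = NULL) {
  family <- match.arg(family)
  eidx <- edge_index(conn$W)
  E <- length(eidx)
  need_bins <- family %in% c("G", "GT")
  need_part <- family %in% c("T", "GT")
  if (need_bins) {
    if (is.null(bins)) stop("family ", family, " requires length bins")
    if (bins$n_edges != E) {
      stop("bin specification does not match this connectome's edge set")
    }
  }
  if (need_part) {
    if (is.null(partition)) stop("family ", family,
                                 " requires a community partition")
    if (length(partition) != nrow(conn$W)) {
      stop("community partition does not cover all nodes of this connectome")
    }
  }
  key <- rep("all", E)
  tags <- character(0)
  if (need_bins) {
    key <- paste(key, sprintf("bin%03d", bins$bin_of_edge))
    tags <- c(tags, "geometry")
  }
  if (need_part) {
    ij <- arrayInd(eidx, dim(conn$W))
    ci <- partition[ij[, 1]]; cj <- partition[ij[, 2]]
    block <- ifelse(ci == cj, sprintf("com%03d", ci), "between")
    rc <- richclub_categories(conn)
    key <- paste(key, block, sprintf("rc%04d", rc))
    tags <- c(tags, "community", "richclub")
  }
  .cells_from_key(conn, key, tags, family)
}

#' Permute weights within cells
#'
#' Uniformly randomly permutes the non-zero weights across the edge slots of
#' every cell of size two or more; singleton cells, the length matrix and the
#' binary support are left unchanged.
#'
#' @param conn parent [connectome()].
#' @param cells a `cell_partition` built on `conn`.
#' @param seed integer RNG seed.
#' @return a `surrogate_sample`: `connectome` (permuted weights),
#'   `family`, `seed`, `permutable_fraction`, `adjusted = FALSE`.
#' @export
permute_within_cells <- function(conn, cells, seed = 1) {
  if (!inherits(cells, "cell_partition")) stop("cells must be a cell_partition")
  if (cells$n_nodes != nrow(conn$W) ||
      !identical(cells$edge_idx, edge_index(conn$W))) {
    stop("cell partition does not match this connectome")
  }
  eidx <- cells$edge_idx
  w <- conn$W[eidx]
  with_seed(seed, {
    for (cell in cells$cells) {
      if (length(cell) >= 2) w[cell] <- w[cell][sample.int(length(cell))]
    }
  })
  W2 <- conn$W * 0
  W2[eidx] <- w
  W2 <- W2 + t(W2)
  out <- conn
  out$W <- W2
  structure(list(connectome = out, family = cells$family, seed = seed,
                 permutable_fraction = cells$permutable_fraction,
                 adjusted = FALSE),
            class = "surrogate_sample")
}

#' Adjust surrogate weights to preserve the strength sequence
#'
#' Iterative multiplicative correction: at each iteration every edge weight
#' is rescaled by the geometric mean of its endpoints' target/current
#' strength ratios, driving the node strengths of the surrogate to the
#' parent's strength sequence. Support and weight positivity are preserved
#' exactly; individual weight values (and hence their global rank order)
#' change by the smooth per-node rescaling.
#'
#' @param sample a `surrogate_sample` (or a [connectome()]).
#' @param target_strengths parent node strengths (positive); defaults must be
#'   supplied by the caller since the sample no longer knows its parent.
#' @param tol maximal relative strength error at convergence (default 1e-3).
#' @param max_iter iteration cap (default 100); non-convergence is reported
#'   with a warning, not a failure.
#' @return the sample with adjusted `connectome`, `adjusted = TRUE`,
#'   `strength_error` (achieved max relative error) and `iterations`.
#' @export
adjust_strength_sequence <- function(sample, target_strengths,
                                     tol = 1e-3, max_iter = 100) {
  conn <- if (inherits(sample, "surrogate_sample")) sample$connectome
          else sample
  if (any(target_strengths <= 0)) stop("target strengths must be positive")
  eidx <- edge_index(conn$W)
  ij <- arrayInd(eidx, dim(conn$W))
  i <- ij[, 1]; j <- ij[, 2]
  w <- conn$W[eidx]
  W <- conn$W
  err <- Inf
  iter <- 0L
  while (iter < max_iter) {
    s_cur <- rowSums(W)
    err <- max(abs(s_cur - target_strengths) / target_strengths)
    if (err < tol) break
    iter <- iter + 1L
    ratio <- target_strengths / s_cur
    w <- w * sqrt(ratio[i] * ratio[j])
    W[] <- 0
    W[eidx] <- w
    W <- W + t(W)
  }
  if (err >= tol) {
    warning(sprintf(paste0("strength adjustment did not reach tol %.1e in ",
                           "%d iterations (achieved %.2e)"),
                    tol, max_iter, err))
  }
  conn$W <- W
  if (inherits(sample, "surrogate_sample")) {
    sample$connectome <- conn
    sample$adjusted <- TRUE
    sample$strength_error <- err
    sample$iterations <- iter
    sample
  } else {
    structure(list(connectome = conn, family = NA_character_, seed = NA,
                   permutable_fraction = NA_real_, adjusted = TRUE,
                   strength_error = err, iterations = iter),
              class = "surrogate_sample")
  }
}

#' Generate one constrained surrogate sample
#'
#' Permutes weights within the given cells and (by default) applies the
#' strength-sequence correction toward the parent's strengths.
#'
#' @param conn parent [connectome()].
#' @param cells `cell_partition` from [build_cells()] or [make_rsn_pair()].
#' @param seed integer RNG seed.
#' @param adjust apply [adjust_strength_sequence()].
#' @param tol,max_iter passed to the strength adjustment.
#' @return a `surrogate_sample`.
#' @export
make_surrogate <- function(conn, cells, seed = 1, adjust = TRUE,
                           tol = 1e-3, max_iter = 100) {
  smp <- permute_within_cells(conn, cells, seed = seed)
  if (adjust) {
    smp <- adjust_strength_sequence(smp, target_strengths = rowSums(conn$W),
                                    tol = tol, max_iter = max_iter)
  }
  smp
}

#' Build an RSN-constrained main/control cell-partition pair
#'
#' Main: the jointly geometry- and topology-constrained cells restricted to
#' edges incident to at least one node of the RSN of interest (all other
#' edges frozen). Control: the same cells restricted to edges NOT incident
#' to the RSN; random non-incident edges are then additionally frozen until
#' the control's permutable edge count matches the main's (exactly when the
#' cell-size arithmetic permits, off by at most one edge otherwise), so the
#' permuted-edge fractions of the pair are equalized.
#'
#' @param conn parent [connectome()] with RSN labels.
#' @param gt_cells the GT `cell_partition` from [build_cells()].
#' @param rsn RSN label of interest (one of [rsn_levels]).
#' @param seed integer RNG seed for the random down-selection.
#' @return list with `main` and `control` `cell_partition`s and their
#'   permutable fractions.
#' @export
make_rsn_pair <- function(conn, gt_cells, rsn, seed = 1) {
  rsn <- match.arg(rsn, rsn_levels)
  labs <- as.character(conn$nodes$rsn)
  if (!any(labs == rsn, na.rm = TRUE)) {
    stop("RSN ", rsn, " has no nodes in this connectome")
  }
  eidx <- gt_cells$edge_idx
  E <- gt_cells$n_edges
  ij <- arrayInd(eidx, dim(conn$W))
  in_rsn <- which(labs == rsn)
  incident <- ij[, 1] %in% in_rsn | ij[, 2] %in% in_rsn

  gt_key <- character(E)
  for (ci in seq_along(gt_cells$cells)) gt_key[gt_cells$cells[[ci]]] <- ci

  pool_count <- function(key, active) {
    k <- key[active]
    tab <- table(k)
    sum(tab[tab >= 2])
  }
  p_main <- pool_count(gt_key, incident)
  if (p_main == 0) stop("RSN ", rsn, " has no incident permutable edges")
  p_ctrl <- pool_count(gt_key, !incident)
  if (p_ctrl == 0) {
    stop("control pool is empty: every permutable edge touches RSN ", rsn)
  }
  if (p_ctrl < p_main) {
    stop(sprintf(paste0("control pool (%d permutable edges) smaller than ",
                        "main pool (%d); cannot equalize"), p_ctrl, p_main))
  }

  # freeze random non-incident edges until the permutable counts match
  active <- !incident
  with_seed(seed, {
    delta <- p_ctrl - p_main
    while (delta > 0) {
      k <- gt_key[active]
      tab <- table(k)
      big <- names(tab[tab >= 3])
      two <- names(tab[tab == 2])
      if (delta == 1 && length(big) > 0) {
        cand <- which(active & gt_key %in% big)
      } else {
        cand <- which(active & gt_key %in% c(big, two))
      }
      if (length(cand) == 0) break
      e <- cand[sample.int(length(cand), 1)]
      sz <- sum(active & gt_key == gt_key[e])
      active[e] <- FALSE
      delta <- delta - if (sz == 2) 2L else 1L
    }
  })

  key_main <- ifelse(incident, gt_key, paste0("frozen", seq_len(E)))
  key_ctrl <- ifelse(active, gt_key, paste0("frozen", seq_len(E)))
  main <- .cells_from_key(conn, key_main,
                          c(gt_cells$constraint_tags, "rsn_main"),
                          paste0("RSN_main_", rsn))
  ctrl <- .cells_from_key(conn, key_ctrl,
                          c(gt_cells$constraint_tags, "rsn_control"),
                          paste0("RSN_control_", rsn))
  list(main = main, control = ctrl,
       fraction_main = main$permutable_fraction,
       fraction_control = ctrl$permutable_fraction)
}
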