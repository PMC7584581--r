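#' Construct a structural connectome object
#'
#' Bundles the symmetric weight matrix `W`, the symmetric streamline-length
#' matrix `L` (mm, positive exactly where `W` is non-zero) and the node
#' metadata table into a validated `connectome` object.
#'
#' @param W n x n non-negative symmetric weight matrix with zero diagonal.
#' @param L n x n symmetric length matrix (mm); `L[i,j] > 0` iff `W[i,j] > 0`.
#' @param nodes data.frame with columns `node_id` (0-based, unique),
#'   `x`, `y`, `z` (mm), `structural_community` (integer) and `rsn`
#'   (one of [rsn_levels], or `NA` before labelling).
#' @param validate check all invariants (symmetry, support identity,
#'   connectedness of the binarized graph).
#' @return An object of class `connectome` with elements `W`, `L`, `nodes`
#'   and `density` (fraction of non-zero upper-triangle entries).
#' @export
connectome <- function(W, L, nodes, validate = TRUE) {
  W <- unname(as.matrix(W))
  L <- unname(as.matrix(L))
  obj <- structure(
    list(W = W, L = L, nodes = nodes,
         density = mean(W[upper.tri(W)] > 0)),
    class = "connectome")
  if (validate) validate_connectome(obj)
  obj
}

#' Validate connectome invariants
#'
#' Checks squareness, symmetry, zero diagonal, non-negativity of `W`, the
#' `W`/`L` support identity, node-table consistency and connectedness of the
#' binarized graph. Called by [connectome()] and [read_connectome()].
#'
#' @param x a `connectome` object.
#' @param tol asymmetry tolerance.
#' @return `x`, invisibly; errors name the violated invariant.
#' @export
validate_connectome <- function(x, tol = 1e-12) {
  W <- x$W; L <- x$L; nodes <- x$nodes
  n <- nrow(W)
  if (ncol(W) != n || !all(dim(L) == n)) {
    stop("W and L must be square matrices of equal size")
  }
  if (max(abs(W - t(W))) > tol) stop("W is not symmetric within tolerance")
  if (max(abs(L - t(L))) > tol) stop("L is not symmetric within tolerance")
  if (any(diag(W) != 0)) stop("diagonal of W must be zero")
  if (any(W < 0)) stop("W must be non-negative")
  bad <- which((W > 0) != (L > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("W/L support mismatch at node pair (%d, %d)",
                 bad[1, 1], bad[1, 2]))
  }
  if (!is.null(nodes)) {
    if (nrow(nodes) != n) stop("node table size does not match W")
    if (anyDuplicated(nodes$node_id) || !setequal(nodes$node_id, 0:(n - 1))) {
      stop("node_ids must be unique integers 0..n-1")
    }
  }
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  if (igraph::components(g)$no != 1) {
    stop("binarized connectome is not a single connected component")
  }
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$W)
  cat(sprintf("<connectome> %d nodes, %d edges, density %.3f\n",
              n, sum(x$W[upper.tri(x$W)] > 0), x$density))
  if (!is.null(x$nodes$rsn) && !all(is.na(x$nodes$rsn))) {
    cat("  RSN counts:",
        paste(sprintf("%s=%d", rsn_levels,
                      tabulate(match(x$nodes$rsn, rsn_levels),
                               length(rsn_levels))), collapse = " "), "\n")
  }
  invisible(x)
}

# upper-triangle (i < j) edge index pairs of the non-zero support
edge_index <- function(W) {
  which(upper.tri(W) & W > 0)
}

#' Spatial extents of the synthetic geometry
#'
#' Bounding-box limits (mm) that every coordinate generated by
#' [generate_geometry()] falls inside: brain-scale, two mirrored hemispheres
#' along the x axis.
#' @return list with `x`, `y`, `z` ranges (mm).
#' @export
geometry_extents <- function() {
  list(x = c(-64, 64), y = c(-82, 82), z = c(-58, 58))
}

#' Generate mirrored two-hemisphere node geometry
#'
#' Samples node coordinates on two mirrored hemispheric ellipsoidal shells,
#' emulating cortical spatial embedding at brain scale. The right hemisphere
#' mirrors left-hemisphere coordinates through the midline, so within- and
#' between-hemisphere distances span a broad, bimodal-ish range.
#'
#' @param n_nodes number of nodes (>= 4).
#' @param seed integer RNG seed; identical `(n_nodes, seed)` gives identical
#'   output.
#' @return node table (data.frame) with `node_id` (0-based), `x`, `y`, `z`
#'   in mm, `hemisphere` ("L"/"R"), placeholder `structural_community = 1`
#'   and `rsn = NA`.
#' @export
generate_geometry <- function(n_nodes, seed = 1) {
  if (n_nodes < 4) stop("n_nodes must be at least 4")
  semi <- c(30, 80, 55)   # hemisphere shell semi-axes, mm
  gap <- 2                # interhemispheric margin, mm
  with_seed(seed, {
    n_left <- ceiling(n_nodes / 2)
    n_right <- n_nodes - n_left
    # unit directions, then a thick shell radius
    u <- matrix(rnorm(3 * n_left), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- runif(n_left, 0.75, 1)
    pts <- u * rad * rep(semi, each = n_left)
    left <- cbind(x = -(gap + abs(pts[, 1])), y = pts[, 2], z = pts[, 3])
    right <- left[seq_len(n_right), , drop = FALSE]
    right[, 1] <- -right[, 1]
    coords <- rbind(left, right)
    data.frame(node_id = 0:(n_nodes - 1),
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               hemisphere = rep(c("L", "R"), c(n_left, n_right)),
               structural_community = 1L,
               rsn = NA_character_)
  })
}

#' Generate a synthetic structural connectome
#'
#' Builds a weighted, spatially embedded, modular connectome with a weighted
#' rich club on top of a node geometry, emulating the statistical structure
#' of an empirical group connectome: candidate weights follow
#' `w = exp(-L / decay_scale) * community_multiplier * hub_multiplier *
#' lognormal noise`, the weakest candidates are thresholded away to hit the
#' target density, and maximum-weight bridging edges are re-added if the
#' graph disconnects.
#'
#' @param nodes node table from [generate_geometry()].
#' @param target_density fraction of node pairs connected (0, 1).
#' @param decay_scale exponential length scale of weight decay, mm
#'   (`Inf` removes the weight-length relationship).
#' @param n_communities number of spatially contiguous structural communities
#'   (k-means on coordinates; >= 2).
#' @param hub_fraction fraction of nodes designated hubs; hub-incident edges
#'   get boosted weights, hub-hub edges doubly so.
#' @param seed integer RNG seed.
#' @param tortuosity streamline length = Euclidean distance x tortuosity.
#' @param community_boost within-community weight multiplier.
#' @param hub_boost hub-hub weight multiplier (one hub endpoint gets its
#'   square root).
#' @param noise_sdlog sdlog of the multiplicative lognormal weight noise.
#' @param max_length longest admissible streamline (mm); candidate edges
#'   beyond it are excluded, keeping the length distribution compact the way
#'   consensus-thresholded group connectomes are.
#' @return a validated [connectome()] whose node table carries the realized
#'   `structural_community` labels.
#' @export
generate_connectome <- function(nodes, target_density = 0.19,
                                decay_scale = 60, n_communities = 4,
                                hub_fraction = 0.15, seed = 1,
                                tortuosity = 1.2, community_boost = 2,
                                hub_boost = 5, noise_sdlog = 0.8,
                                max_length = 120) {
  if (target_density <= 0 || target_density >= 1) {
    stop("target_density must be in (0, 1)")
  }
  if (n_communities < 2) stop("n_communities must be at least 2")
  n <- nrow(nodes)
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  D <- as.matrix(dist(coords))
  L <- D * tortuosity
  npairs <- n * (n - 1) / 2
  m_target <- round(target_density * npairs)
  if (m_target < n - 1) {
    stop(sprintf(paste0("target density %.3f yields %d edges but %d are ",
                        "needed for connectivity on %d nodes"),
                 target_density, m_target, n - 1, n))
  }

  with_seed(seed, {
    km <- kmeans(coords, centers = n_communities, nstart = 10)
    comm <- km$cluster
    n_hub <- max(2, round(hub_fraction * n))
    hubs <- sample.int(n, n_hub)
    is_hub <- seq_len(n) %in% hubs

    mult <- matrix(1, n, n)
    same_comm <- outer(comm, comm, "==")
    mult[same_comm] <- community_boost
    hub_pow <- outer(is_hub, is_hub, "+") / 2
    mult <- mult * hub_boost^hub_pow

    ut <- upper.tri(L)
    noise <- matrix(0, n, n)
    noise[ut] <- rlnorm(npairs, meanlog = 0, sdlog = noise_sdlog)
    decay <- if (is.finite(decay_scale)) exp(-L / decay_scale) else
      matrix(1, n, n)
    w_cand <- decay * mult * noise * (L <= max_length)

    cand <- w_cand[ut]
    if (sum(cand > 0) < m_target) {
      stop(sprintf(paste0("only %d admissible candidate edges for a target ",
                          "of %d; density unreachable under the length cap"),
                   sum(cand > 0), m_target))
    }
    keep_thr <- sort(cand, decreasing = TRUE)[m_target]
    W <- matrix(0, n, n)
    W[ut] <- ifelse(cand >= keep_thr & cand > 0, cand, 0)
    W <- W + t(W)

    # re-add maximum-weight bridging edges if the graph disconnected
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    memb <- igraph::components(g)$membership
    while (max(memb) > 1) {
      cross <- outer(memb, memb, "!=") & ut & W == 0 & w_cand > 0
      if (!any(cross)) stop("cannot connect graph: no bridging candidates")
      idx <- which(cross)
      add <- idx[which.max(w_cand[idx])]
      W[add] <- w_cand[add]
      W <- pmax(W, t(W))
      g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
      memb <- igraph::components(g)$membership
    }
    realized <- mean(W[ut] > 0)
    if (abs(realized - target_density) / target_density > 0.1) {
      stop(sprintf("realized density %.3f outside 10%% of target %.3f",
                   realized, target_density))
    }
    L_out <- ifelse(W > 0, L, 0)
    nodes$structural_community <- as.integer(comm)
    connectome(W, L_out, nodes)
  })
}

#' Assign resting-state-network labels to nodes
#'
#' Distributes the seven RSN labels over nodes in spatially contiguous
#' blocks along the posterior-anterior axis (VIS most posterior, DMN most
#' anterior), with counts matching `proportions` by largest-remainder
#' rounding. A compact posterior VIS block gives the visual network the
#' highest within-RSN edge density under the distance-decaying generator.
#'
#' @param nodes node table.
#' @param proportions named numeric 7-vector over [rsn_levels], summing to 1.
#' @param seed integer seed for the positional jitter that varies block
#'   boundaries between realizations.
#' @param jitter_sd sd (mm) of the jitter added to the anterior-posterior
#'   score before block assignment.
#' @return `nodes` with the `rsn` column filled (factor over [rsn_levels]).
#' @export
assign_rsn_labels <- function(nodes,
                              proportions = c(CON = 0.14, DMN = 0.21,
                                              LIM = 0.09, DAN = 0.11,
                                              VAN = 0.11, SMN = 0.14,
                                              VIS = 0.20),
                              seed = 1, jitter_sd = 2) {
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (is.null(names(proportions))) names(proportions) <- rsn_levels
  if (!setequal(names(proportions), rsn_levels)) {
    stop("proportions must be named over the seven RSN labels")
  }
  n <- nrow(nodes)
  if (n < length(rsn_levels)) stop("fewer nodes than RSN labels")
  # largest-remainder apportionment
  raw <- proportions[rsn_levels] * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  # posterior -> anterior block order
  block_order <- c("VIS", "DAN", "SMN", "VAN", "CON", "LIM", "DMN")
  with_seed(seed, {
    score <- nodes$y + rnorm(n, sd = jitter_sd)
    idx <- order(score)
    lab <- character(n)
    pos <- 1
    for (r in block_order) {
      k <- counts[[r]]
      if (k > 0) {
        lab[idx[pos:(pos + k - 1)]] <- r
        pos <- pos + k
      }
    }
    nodes$rsn <- factor(lab, levels = rsn_levels)
    nodes
  })
}

#' Generate a complete synthetic connectome with RSN labels
#'
#' Convenience wrapper chaining [generate_geometry()],
#' [generate_connectome()] and [assign_rsn_labels()] under one seed.
#'
#' @param n_nodes number of nodes (default 114, the parcellation size the
#'   analysis assumes; 57 is the reduced fast-test profile).
#' @param seed integer RNG seed.
#' @param ... passed to [generate_connectome()].
#' @param rsn_proportions passed to [assign_rsn_labels()].
#' @return a validated [connectome()].
#' @export
synthetic_connectome <- function(n_nodes = 114, seed = 1,
                                 rsn_proportions = NULL, ...) {
  nodes <- generate_geometry(n_nodes, seed = seed)
  conn <- generate_connectome(nodes, seed = seed + 1, ...)
  args <- list(nodes = conn$nodes, seed = seed + 2)
  if (!is.null(rsn_proportions)) args$proportions <- rsn_proportions
  conn$nodes <- do.call(assign_rsn_labels, args)
  conn
}

#' Within-RSN structural edge densities
#'
#' Edge density of the binarized connectome restricted to node pairs inside
#' each RSN.
#' @param conn a [connectome()] with RSN labels.
#' @return named numeric vector over [rsn_levels] (`NA` for RSNs with < 2
#'   nodes).
#' @export
rsn_densities <- function(conn) {
  rsn <- as.character(conn$nodes$rsn)
  vapply(rsn_levels, function(r) {
    idx <- which(rsn == r)
    if (length(idx) < 2) return(NA_real_)
    sub <- conn$W[idx, idx]
    mean(sub[upper.tri(sub)] > 0)
  }, numeric(1))
}
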