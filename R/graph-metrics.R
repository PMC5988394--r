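check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(adj != 0 & adj != 1)) stop("adjacency must be binary")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  adj
}

adj_to_graph <- function(adj) {
  e <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  igraph::make_graph(as.vector(t(e)), n = nrow(adj), directed = FALSE)
}

#' Binary clustering coefficient per node
#'
#' `CC_i = 2 t_i / (k_i (k_i - 1))` where `t_i` is the number of triangles
#' through node i and `k_i` its degree. Nodes with degree < 2 have no
#' neighbor pairs; their CC is defined as 0 (the standard toolbox
#' convention), keeping the metric defined at every node and frame.
#'
#' @param adj symmetric hollow binary adjacency matrix.
#' @return numeric vector in \[0, 1\], one value per node.
#' @export
clustering_coefficient <- function(adj) {
  adj <- check_adjacency(adj)
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  unname(cc)
}

#' Louvain community detection with a resolution parameter
#'
#' Greedy multilevel optimization of Newman-Girvan modularity with
#' resolution gamma, `Q = sum_c [ e_c / m - gamma (d_c / 2m)^2 ]`. The
#' algorithm's sweep order and tie-breaks are randomized, so the partition
#' is a function of `seed`; Q is re-evaluated from the returned labels
#' under the same convention.
#'
#' @param adj symmetric hollow binary adjacency matrix.
#' @param gamma resolution (> 0); gamma > 1 favors more, smaller modules.
#' @param seed integer RNG seed controlling tie-breaking.
#' @return a `partition`: list with `labels` (per-node integer module ids),
#'   `n_modules`, `Q`, `gamma`, `seed`.
#' @export
louvain_partition <- function(adj, gamma = 2, seed = 1L) {
  adj <- check_adjacency(adj)
  if (gamma <= 0) stop("gamma must be positive")
  g <- adj_to_graph(adj)
  if (igraph::ecount(g) == 0L) {
    return(structure(list(labels = rep(1L, nrow(adj)), n_modules = 1L,
                          Q = 0, gamma = gamma, seed = seed),
                     class = "partition"))
  }
  labels <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = gamma))
  })
  labels <- as.integer(labels)
  Q <- modularity_score(adj, labels, gamma)
  structure(list(labels = labels, n_modules = length(unique(labels)),
                 Q = Q, gamma = gamma, seed = seed),
            class = "partition")
}

#' Modularity of a labeling at resolution gamma
#'
#' Direct evaluation of `Q = sum_c [ e_c / m - gamma (d_c / 2m)^2 ]` from
#' an adjacency matrix and module labels, independent of any community
#' detection routine.
#'
#' @param adj symmetric hollow binary adjacency matrix.
#' @param labels per-node module ids.
#' @param gamma resolution parameter.
#' @return modularity Q (0 for an empty graph).
#' @export
modularity_score <- function(adj, labels, gamma = 1) {
  adj <- check_adjacency(adj)
  m2 <- sum(adj)  # 2m
  if (m2 == 0) return(0)
  Q <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(adj[idx, , drop = FALSE])
    Q <- Q + e_c / (m2 / 2) - gamma * (d_c / m2)^2
  }
  Q
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d modules, Q = %.4f (gamma = %g)\n",
              x$n_modules, x$Q, x$gamma))
  invisible(x)
}

#' Participation coefficient per node
#'
#' `PC_i = 1 - sum_m (k_i(m) / k_i)^2` over the modules m of a partition,
#' where `k_i(m)` counts node i's links into module m. 0 means all links
#' fall in a single module (whether or not it is the node's own); values
#' near 1 mean links spread over many modules. Isolated nodes (k = 0) get
#' PC = 0. Invariant under module relabeling.
#'
#' @param adj symmetric hollow binary adjacency matrix.
#' @param partition a `partition` (or bare integer label vector).
#' @return numeric vector in \[0, 1), one value per node.
#' @export
participation_coefficient <- function(adj, partition) {
  adj <- check_adjacency(adj)
  labels <- if (inherits(partition, "partition")) partition$labels
            else as.integer(partition)
  if (length(labels) != nrow(adj))
    stop("partition must cover all nodes")
  k <- rowSums(adj)
  acc <- numeric(nrow(adj))
  for (c in unique(labels)) {
    k_im <- rowSums(adj[, labels == c, drop = FALSE])
    acc <- acc + ifelse(k > 0, (k_im / pmax(k, 1))^2, 0)
  }
  pc <- ifelse(k == 0, 0, 1 - acc)
  unname(pc)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered node pairs of a connected
#' binary graph. Errors on disconnected input, reporting component sizes.
#'
#' @param adj symmetric hollow binary adjacency matrix.
#' @return a single number >= 1 (for any graph with >= 2 nodes).
#' @export
characteristic_path_length <- function(adj) {
  adj <- check_adjacency(adj)
  g <- adj_to_graph(adj)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("graph is disconnected; component sizes: ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  D <- igraph::distances(g)
  mean(D[upper.tri(D)])
}

#' Small-worldness sigma
#'
#' `sigma = (CC / CC_rand) / (L / L_rand)` where CC is the graph's mean
#' clustering coefficient, L its characteristic path length, and the
#' reference values are means over `n_random` degree-preserving rewired
#' surrogates (double-edge swaps, 10 |E| swap attempts each). sigma > 1
#' indicates a small-world topology: clustered yet short paths. Rewired
#' surrogates that come out disconnected contribute their mean finite
#' inter-node distance.
#'
#' @param adj symmetric hollow binary connected adjacency matrix.
#' @param n_random number of rewired reference graphs (default 500).
#' @param seed integer RNG seed.
#' @return sigma, with attributes `cc_ratio` and `l_ratio`.
#' @export
small_worldness <- function(adj, n_random = 500L, seed = 1L) {
  adj <- check_adjacency(adj)
  g <- adj_to_graph(adj)
  if (igraph::components(g)$no > 1L) stop("graph must be connected")
  cc_obs <- mean(clustering_coefficient(adj))
  l_obs <- characteristic_path_length(adj)
  with_seed(seed, {
    ref <- vapply(seq_len(n_random), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(
        niter = 10 * igraph::ecount(g)))
      a <- as.matrix(igraph::as_adjacency_matrix(gr))
      Dm <- igraph::distances(gr)
      c(mean(clustering_coefficient(a)),
        mean(Dm[upper.tri(Dm)][is.finite(Dm[upper.tri(Dm)])]))
    }, numeric(2L))
    cc_rand <- mean(ref[1L, ]); l_rand <- mean(ref[2L, ])
    if (cc_rand == 0) stop("rewired reference graphs have no triangles; ",
                           "sigma undefined")
    sigma <- (cc_obs / cc_rand) / (l_obs / l_rand)
    attr(sigma, "cc_ratio") <- cc_obs / cc_rand
    attr(sigma, "l_ratio") <- l_obs / l_rand
    sigma
  })
}

#' Consensus partition over a set of partitions
#'
#' Builds the node-by-node agreement matrix (fraction of partitions placing
#' each pair in the same module), zeroes entries below `tau`, and
#' re-clusters the thresholded agreement matrix (weighted Louvain,
#' gamma = 1) repeatedly until all re-clustering runs agree.
#'
#' @param partitions list of `partition` objects (or label vectors) over
#'   the same node set, length >= 2.
#' @param tau agreement threshold in (0, 1).
#' @param seed integer RNG seed.
#' @param n_rep re-clustering runs per iteration.
#' @param max_iter maximum consensus iterations.
#' @return a `partition` (Q evaluated on the final agreement matrix).
#' @export
consensus_partition <- function(partitions, tau = 0.5, seed = 1L,
                                n_rep = 10L, max_iter = 20L) {
  if (length(partitions) < 2L) stop("need at least 2 partitions")
  label_mat <- vapply(partitions, function(p) {
    if (inherits(p, "partition")) p$labels else as.integer(p)
  }, integer(length_partition(partitions[[1L]])))
  N <- nrow(label_mat)
  agree <- agreement_matrix(label_mat)
  if (tau >= max(agree[upper.tri(agree)]))
    stop("tau (", tau, ") >= maximum pairwise agreement (",
         max(agree[upper.tri(agree)]), "); nothing survives thresholding")
  A <- agree * (agree >= tau)
  for (iter in seq_len(max_iter)) {
    runs <- with_seed(seed + iter, {
      lapply(seq_len(n_rep), function(r) {
        g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                                 weighted = TRUE)
        as.integer(igraph::membership(igraph::cluster_louvain(g)))
      })
    })
    canon <- lapply(runs, canonical_labels)
    if (length(unique(canon)) == 1L) {
      labels <- canon[[1L]]
      Q <- weighted_modularity(A, labels)
      return(structure(list(labels = labels,
                            n_modules = length(unique(labels)),
                            Q = Q, gamma = 1, seed = seed),
                       class = "partition"))
    }
    agree <- agreement_matrix(do.call(cbind, runs))
    A <- agree * (agree >= tau)
  }
  stop("consensus did not converge in ", max_iter, " iterations")
}

length_partition <- function(p) {
  if (inherits(p, "partition")) length(p$labels) else length(p)
}

agreement_matrix <- function(label_mat) {
  N <- nrow(label_mat)
  agree <- matrix(0, N, N)
  for (k in seq_len(ncol(label_mat))) {
    same <- outer(label_mat[, k], label_mat[, k], "==") * 1
    agree <- agree + same
  }
  agree <- agree / ncol(label_mat)
  diag(agree) <- 0
  agree
}

# relabel modules by order of first appearance so identical clusterings
# compare equal regardless of arbitrary ids
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

weighted_modularity <- function(W, labels, gamma = 1) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  Q <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    Q <- Q + sum(W[idx, idx]) / m2 - gamma * (sum(W[idx, ]) / m2)^2
  }
  Q
}
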