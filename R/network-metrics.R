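net_weights <- function(net) {
  if (inherits(net, "ggm_network")) net$weights else as.matrix(net)
}

net_nodes <- function(net) {
  if (inherits(net, "ggm_network")) return(net$nodes)
  colnames(net) %||% sprintf("V%02d", seq_len(ncol(net)))
}

abs_graph <- function(W, nodes) {
  A <- abs(W)
  dimnames(A) <- list(nodes, nodes)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Node centralities of a weighted network
#'
#' Strength is the sum of absolute incident edge weights. For paths, an
#' edge's length is the inverse of its absolute weight; closeness is the
#' inverse of the summed shortest-path distances to all other nodes (0 when
#' any node is unreachable), and betweenness counts the geodesics passing
#' through a node, splitting ties fractionally (Brandes convention).
#' Each index is also returned z-standardised across nodes.
#'
#' @param net a `ggm_network` or symmetric weight matrix (>= 2 nodes).
#' @return data frame: node, strength, closeness, betweenness and their
#'   z-scores.
#' @export
centralities <- function(net) {
  W <- net_weights(net)
  nodes <- net_nodes(net)
  p <- ncol(W)
  if (p < 2) stop_arg("need at least 2 nodes")
  strength <- rowSums(abs(W))
  if (all(W == 0)) {
    closeness <- betweenness <- rep(0, p)
  } else {
    g <- abs_graph(W, nodes)
    len <- 1 / igraph::E(g)$weight
    D <- igraph::distances(g, weights = len)
    dsum <- rowSums(D) # diagonal is 0
    closeness <- ifelse(is.finite(dsum), 1 / dsum, 0)
    betweenness <- igraph::betweenness(g, weights = len, directed = FALSE)
  }
  data.frame(node = nodes,
             strength = strength,
             closeness = closeness,
             betweenness = as.numeric(betweenness),
             z_strength = zscore(strength),
             z_closeness = zscore(closeness),
             z_betweenness = zscore(betweenness),
             row.names = NULL)
}

resolve_membership <- function(partition, nodes) {
  if (is.list(partition) && !is.null(partition$membership)) {
    partition <- partition$membership
  }
  if (!is.null(names(partition))) partition <- partition[nodes]
  if (length(partition) != length(nodes) || anyNA(partition)) {
    stop_arg("partition must label every node")
  }
  as.integer(factor(partition))
}

#' Weighted Newman modularity of a partition
#'
#' On the absolute-weight adjacency `A`,
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)` with
#' `k` the node strengths and `2m` the total weight. Q of the single
#' all-in-one community is exactly 0; Q is at most 1.
#'
#' @param net a `ggm_network` or weight matrix.
#' @param partition community labels (vector, or an igraph communities
#'   object).
#' @return modularity score Q.
#' @export
modularity_q <- function(net, partition) {
  W <- net_weights(net)
  nodes <- net_nodes(net)
  memb <- resolve_membership(partition, nodes)
  A <- abs(W)
  diag(A) <- 0
  two_m <- sum(A)
  if (two_m == 0) stop_arg("empty network: modularity undefined")
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - tcrossprod(k) / two_m) * same) / two_m
}

#' Community detection by multi-algorithm modularity maximisation
#'
#' Runs three algorithms on the absolute-weight graph — exact modularity
#' maximisation ("optimal"), an annealed Potts-model search ("spinglass",
#' run per connected component), and 4-step random-walk agglomeration
#' ("walktrap") — and returns the partition with the highest modularity as
#' recomputed by [modularity_q()]. Deterministic under `seed`. Structures
#' with Q below `weak_threshold` are flagged as weak.
#'
#' @param net a `ggm_network` or weight matrix.
#' @param methods subset of c("optimal", "spinglass", "walktrap").
#' @param seed RNG seed for the annealed search.
#' @param weak_threshold Q below which community structure is reported
#'   weak (conventionally 0.3).
#' @return a `community_partition`: `membership` (named), `Q`,
#'   `algorithm`, `weak`, `all_Q` (per-algorithm scores).
#' @export
detect_communities <- function(net,
                               methods = c("optimal", "spinglass", "walktrap"),
                               seed = 1, weak_threshold = 0.3) {
  methods <- match.arg(methods, several.ok = TRUE)
  W <- net_weights(net)
  nodes <- net_nodes(net)
  p <- length(nodes)
  if (all(W == 0)) {
    memb <- setNames(rep(1L, p), nodes)
    return(structure(list(membership = memb, Q = NA_real_,
                          algorithm = "none", weak = TRUE,
                          all_Q = setNames(numeric(0), character(0))),
                     class = "community_partition"))
  }
  g <- abs_graph(W, nodes)
  results <- list()
  if ("optimal" %in% methods) {
    co <- igraph::cluster_optimal(g, weights = igraph::E(g)$weight)
    results$optimal <- igraph::membership(co)
  }
  if ("spinglass" %in% methods) {
    comp <- igraph::components(g)
    memb <- integer(p)
    offset <- 0L
    with_seed(seed, {
      for (cc in seq_len(comp$no)) {
        vids <- which(comp$membership == cc)
        if (length(vids) == 1) {
          memb[vids] <- offset + 1L
          offset <- offset + 1L
        } else {
          sub <- igraph::induced_subgraph(g, vids)
          cs <- igraph::cluster_spinglass(sub,
                                          weights = igraph::E(sub)$weight)
          m <- igraph::membership(cs)
          memb[vids] <- offset + as.integer(m)
          offset <- offset + max(as.integer(m))
        }
      }
    })
    results$spinglass <- setNames(memb, nodes)
  }
  if ("walktrap" %in% methods) {
    cw <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                   steps = 4)
    results$walktrap <- igraph::membership(cw)
  }
  qs <- vapply(results, function(m) modularity_q(W, m), numeric(1))
  best <- names(qs)[which.max(qs)]
  memb <- as.integer(factor(results[[best]]))
  names(memb) <- nodes
  structure(list(membership = memb, Q = unname(qs[best]),
                 algorithm = best, weak = unname(qs[best]) < weak_threshold,
                 all_Q = qs),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.3f (%s)%s\n",
              length(unique(x$membership)), x$Q, x$algorithm,
              if (isTRUE(x$weak)) " [weak structure]" else ""))
  invisible(x)
}
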