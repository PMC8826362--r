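nct_statistics <- function(net1, net2) {
  e1 <- upper_tri_vec(net1$weights)
  e2 <- upper_tri_vec(net2$weights)
  edge_diff <- abs(e1 - e2)
  s1 <- rowSums(abs(net1$weights))
  s2 <- rowSums(abs(net2$weights))
  list(M = max(edge_diff),
       global_strength = abs(global_strength(net1) - global_strength(net2)),
       edge_diff = edge_diff,
       strength_diff = abs(s1 - s2))
}

#' Paired permutation comparison of two timepoint networks
#'
#' Tests whether the networks estimated at the two visits differ, against
#' the null that the two time points are exchangeable within subject. Each
#' permutation independently swaps, with probability 1/2 per subject, that
#' subject's two score vectors, and re-estimates both networks with the
#' identical correlation + EBIC-glasso pipeline. Statistics: network
#' structure `M` (maximum absolute edge-weight difference), global strength
#' difference (absolute difference of the summed absolute edge weights),
#' per-edge absolute differences and per-node strength differences — the
#' per-edge/per-node tests deliberately uncorrected for multiplicity.
#' P-values use the add-one convention
#' `(1 + #\{perm >= observed\}) / (1 + iterations)`.
#'
#' @param table complete `cohort_table` with exactly 2 timepoints.
#' @param config a [pipeline_config()].
#' @param nodes scales to include (default: all).
#' @param iterations permutations (default `config$permutations`; a
#'   warning is issued below 100).
#' @param alpha significance level recorded in the result (default
#'   `config$alpha_comparison`).
#' @param seed RNG seed (default `config$seed`).
#' @return an `nct_result`: observed statistics, p-values, permutation
#'   reference distributions, the two networks, `iterations`, `alpha`.
#' @export
nct_paired <- function(table, config = pipeline_config(), nodes = NULL,
                       iterations = NULL, alpha = NULL, seed = NULL) {
  iterations <- iterations %||% config$permutations
  alpha <- alpha %||% config$alpha_comparison
  seed <- seed %||% config$seed
  if (iterations < 100) warning("fewer than 100 permutations: p-values crude")
  if (length(table$timepoints) != 2) {
    stop_arg("paired comparison needs exactly 2 timepoints")
  }
  if (anyNA(table$scores[[1]]) || anyNA(table$scores[[2]])) {
    stop_arg("every subject must be observed at both timepoints (impute first)")
  }
  tp <- table$timepoints
  net1 <- fit_network(table, config, tp[1], nodes)
  net2 <- fit_network(table, config, tp[2], nodes)
  obs <- nct_statistics(net1, net2)
  n <- length(table$subjects)

  n_pairs <- length(obs$edge_diff)
  perm_M <- perm_S <- numeric(iterations)
  perm_edge <- matrix(NA_real_, iterations, n_pairs)
  perm_strength <- matrix(NA_real_, iterations, length(net1$nodes),
                          dimnames = list(NULL, net1$nodes))
  X1 <- table$scores[[tp[1]]]
  X2 <- table$scores[[tp[2]]]
  for (it in seq_len(iterations)) {
    swap <- with_seed(child_seed(seed, it), runif(n) < 0.5)
    tab <- table
    tab$scores[[tp[1]]][swap, ] <- X2[swap, ]
    tab$scores[[tp[2]]][swap, ] <- X1[swap, ]
    p1 <- fit_network(tab, config, tp[1], nodes)
    p2 <- fit_network(tab, config, tp[2], nodes)
    st <- nct_statistics(p1, p2)
    perm_M[it] <- st$M
    perm_S[it] <- st$global_strength
    perm_edge[it, ] <- st$edge_diff
    perm_strength[it, ] <- st$strength_diff
  }
  pval <- function(ref, o) (1 + sum(ref >= o)) / (1 + length(ref))
  p_edge <- vapply(seq_len(n_pairs),
                   function(k) pval(perm_edge[, k], obs$edge_diff[k]),
                   numeric(1))
  p_strength <- vapply(seq_along(net1$nodes),
                       function(k) pval(perm_strength[, k],
                                        obs$strength_diff[k]),
                       numeric(1))
  structure(list(
    observed = obs,
    p_structure = pval(perm_M, obs$M),
    p_global_strength = pval(perm_S, obs$global_strength),
    p_edges = setNames(p_edge, upper_tri_labels(net1$nodes)),
    p_strength = setNames(p_strength, net1$nodes),
    perm_M = perm_M, perm_global_strength = perm_S,
    perm_edges = perm_edge, perm_strength = perm_strength,
    network1 = net1, network2 = net2,
    iterations = iterations, alpha = alpha, seed = seed
  ), class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf(
    "<nct_result> %d permutations, alpha = %g\n  structure M = %.4f (p = %.3f)\n  global strength diff = %.4f (p = %.3f)\n",
    x$iterations, x$alpha, x$observed$M, x$p_structure,
    x$observed$global_strength, x$p_global_strength))
  cat(sprintf("  significant edges: %d, significant strengths: %d (uncorrected, alpha = %g)\n",
              sum(x$p_edges < x$alpha), sum(x$p_strength < x$alpha), x$alpha))
  invisible(x)
}

#' Difference network between two estimated networks
#'
#' Entrywise change in absolute edge weight, `|w2| - |w1|`: positive
#' entries mark associations that grew in absolute value from the first
#' network to the second, negative ones those that shrank. Swapping the
#' inputs negates every entry. The display threshold is metadata used by
#' exports only.
#'
#' @param net1,net2 `ggm_network`s over identical node sets.
#' @param display_threshold absolute-difference display cutoff recorded in
#'   the result (conventionally 0.04).
#' @return a `diff_network`: `nodes`, `weights`, `display_threshold`.
#' @export
difference_network <- function(net1, net2, display_threshold = 0.04) {
  if (!identical(net1$nodes, net2$nodes)) {
    stop_arg("networks must share an identical node set")
  }
  D <- abs(net2$weights) - abs(net1$weights)
  dimnames(D) <- list(net1$nodes, net1$nodes)
  structure(list(nodes = net1$nodes, weights = D,
                 display_threshold = display_threshold),
            class = "diff_network")
}

#' Spearman correlation between the edge weights of two networks
#'
#' Rank correlation over all vectorized upper-triangle node-pair weights
#' (zeros included), with a two-sided p-value.
#'
#' @param net1,net2 `ggm_network`s over identical node sets (>= 3 pairs).
#' @return list: `rho`, `p_value`, `n_pairs`.
#' @export
edge_weight_correlation <- function(net1, net2) {
  if (!identical(net1$nodes, net2$nodes)) {
    stop_arg("networks must share an identical node set")
  }
  e1 <- upper_tri_vec(net1$weights)
  e2 <- upper_tri_vec(net2$weights)
  if (length(e1) < 3) stop_arg("need at least 3 node pairs")
  if (sd(e1) == 0 || sd(e2) == 0) {
    stop_arg("constant edge-weight vector: correlation undefined")
  }
  ct <- suppressWarnings(cor.test(e1, e2, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(e1))
}
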