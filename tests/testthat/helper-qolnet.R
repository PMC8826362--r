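# shared fixtures and independent oracles, all built in code

random_corr <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + p * diag(p)
  cov2cor(S)
}

# build a small cohort table directly from per-timepoint score matrices
make_test_cohort <- function(..., range = c(0, 100), kinds = NULL) {
  scores <- list(...)
  nm <- colnames(scores[[1]])
  kinds <- kinds %||% rep("continuous", length(nm))
  defs <- lapply(seq_along(nm), function(k) {
    if (kinds[k] == "ordinal") {
      scale_definition(nm[k], "ordinal", range = range, levels = 4L)
    } else {
      scale_definition(nm[k], "continuous", range = range)
    }
  })
  cohort_table(scores = scores, scale_defs = defs,
               subjects = sprintf("P%03d", seq_len(nrow(scores[[1]]))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent convex-solver oracle for the graphical lasso: ADMM with
# eigendecomposition-based Theta updates and soft-threshold Z updates
admm_glasso <- function(S, lambda, rho = 1, iters = 2000) {
  p <- ncol(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  Theta <- diag(p)
  for (i in seq_len(iters)) {
    eg <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * rho)) / (2 * rho)
    Theta <- eg$vectors %*% diag(d) %*% t(eg$vectors)
    Zold <- Z
    M <- Theta + U
    Z <- sign(M) * pmax(abs(M) - lambda / rho, 0)
    diag(Z) <- diag(M)  # diagonal unpenalised
    U <- U + Theta - Z
    if (max(abs(Z - Zold)) < 1e-10 && max(abs(Theta - Z)) < 1e-10) break
  }
  list(Theta = Z, W = solve(Z))
}

# exhaustive modularity maximisation over all set partitions (tiny p only)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (part in all_partitions(n - 1)) {
    for (k in seq_along(part)) {
      p2 <- part
      p2[[k]] <- c(p2[[k]], n)
      out[[length(out) + 1L]] <- p2
    }
    part[[length(part) + 1L]] <- n
    out[[length(out) + 1L]] <- part
  }
  out
}

exhaustive_best_modularity <- function(W) {
  p <- ncol(W)
  stopifnot(p <= 8)
  best <- -Inf
  for (part in all_partitions(p)) {
    memb <- integer(p)
    for (k in seq_along(part)) memb[part[[k]]] <- k
    q <- modularity_q(W, memb)
    if (q > best) best <- q
  }
  best
}

# weight matrix helper
wmat <- function(p, edges, nodes = sprintf("V%02d", seq_len(p))) {
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (e in edges) {
    W[e[[1]], e[[2]]] <- W[e[[2]], e[[1]]] <- e[[3]]
  }
  W
}

fake_network <- function(W, n = 487) {
  nodes <- colnames(W) %||% sprintf("V%02d", seq_len(ncol(W)))
  dimnames(W) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = W, lambda_selected = 0.1,
                 gamma = 0.5, n = n,
                 edge_count = sum(W[upper.tri(W)] != 0)),
            class = "ggm_network")
}
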