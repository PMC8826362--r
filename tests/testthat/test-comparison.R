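fast_cfg <- function(...) {
  pipeline_config(correlation = "pearson", n_lambda = 15,
                  lambda_min_ratio = 0.05, glasso_tol = 1e-5, ...)
}

paired_fixture <- function(n = 150, p = 6, seed = 40, identical_tp = FALSE) {
  spec <- make_precision_spec(p, 0.3, weight_range = c(0.2, 0.4), seed = seed)
  defs <- lapply(sprintf("s%d", seq_len(p)), scale_definition,
                 kind = "continuous")
  coh <- generate_cohort(spec, defs, n = n, missing_rate = 0,
                         seed = seed + 1)
  if (identical_tp) {
    coh$scores$M12 <- coh$scores$M0
    coh$miss$M12 <- coh$miss$M0
  }
  coh
}

test_that("identical timepoints give zero statistics and p-values of 1", {
  coh <- paired_fixture(identical_tp = TRUE)
  r <- nct_paired(coh, fast_cfg(), iterations = 120, seed = 3)
  expect_equal(r$observed$M, 0)
  expect_equal(r$observed$global_strength, 0)
  expect_equal(r$p_structure, 1)
  expect_equal(r$p_global_strength, 1)
  expect_true(all(r$p_edges == 1))
  expect_true(all(r$p_strength == 1))
})

test_that("observed structure statistic is the maximum per-edge difference", {
  coh <- paired_fixture()
  r <- nct_paired(coh, fast_cfg(), iterations = 120, seed = 4)
  expect_equal(r$observed$M, max(r$observed$edge_diff))
  expect_true(all(r$p_edges > 0 & r$p_edges <= 1))
  expect_true(all(r$p_strength > 0 & r$p_strength <= 1))
})

test_that("p-values are invariant to relabeling the two timepoints", {
  coh <- paired_fixture(n = 120, p = 5)
  swapped <- coh
  swapped$scores <- list(M0 = coh$scores$M12, M12 = coh$scores$M0)
  swapped$miss <- list(M0 = coh$miss$M12, M12 = coh$miss$M0)
  swapped$timepoints <- c("M0", "M12")
  r1 <- nct_paired(coh, fast_cfg(), iterations = 150, seed = 5)
  r2 <- nct_paired(swapped, fast_cfg(), iterations = 150, seed = 5)
  expect_equal(r1$p_structure, r2$p_structure)
  expect_equal(r1$p_global_strength, r2$p_global_strength)
})

test_that("difference network is zero on equal inputs and antisymmetric on swap", {
  W1 <- wmat(4, list(list(1, 2, 0.301), list(3, 4, -0.2)))
  W2 <- wmat(4, list(list(1, 2, 0.241), list(3, 4, -0.25)))
  n1 <- fake_network(W1); n2 <- fake_network(W2)

  expect_true(all(difference_network(n1, n1)$weights == 0))

  d12 <- difference_network(n1, n2)
  d21 <- difference_network(n2, n1)
  expect_equal(d12$weights, -d21$weights)

  # |0.301| vs |0.241|: the association weakened by 0.060
  expect_equal(abs(d12$weights[1, 2]), 0.060, tolerance = 1e-12)
  # negative edge grew in absolute value
  expect_equal(d12$weights[3, 4], 0.05, tolerance = 1e-12)

  n3 <- fake_network(wmat(3, list(list(1, 2, 0.1))))
  expect_error(difference_network(n1, n3), "node set")
})

test_that("edge-weight correlation hits the rank-correlation limits", {
  set.seed(41)
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- runif(10, -0.3, 0.5)
  W <- W + t(W)
  net <- fake_network(W)
  expect_equal(edge_weight_correlation(net, net)$rho, 1)

  # rank-reversed weights
  v <- W[upper.tri(W)]
  Wr <- matrix(0, 5, 5)
  Wr[upper.tri(Wr)] <- sort(v)[rank(-v)]
  Wr <- Wr + t(Wr)
  expect_equal(edge_weight_correlation(net, fake_network(Wr))$rho, -1)

  flat <- fake_network(matrix(0, 5, 5))
  expect_error(edge_weight_correlation(flat, flat), "constant")
})

test_that("a planted cross-time edge change is detected with high probability", {
  # one strong edge at M0 whose latent partial correlation is removed at M12
  p <- 6; n <- 400
  spec1 <- make_precision_spec(p, 0, seed = 1)
  K1 <- spec1$precision
  K1[1, 2] <- K1[2, 1] <- -0.45   # pcor +0.45 at M0
  spec1$precision <- K1
  defs <- lapply(sprintf("s%d", seq_len(p)), scale_definition,
                 kind = "continuous")
  set.seed(42)
  S1 <- solve(K1); S1 <- S1 / tcrossprod(sqrt(diag(S1)))
  X1 <- matrix(rnorm(n * p), n) %*% chol(S1)
  X2 <- matrix(rnorm(n * p), n)  # independent, empty network
  colnames(X1) <- colnames(X2) <- sprintf("s%d", seq_len(p))
  coh <- make_test_cohort(M0 = X1, M12 = X2, range = c(-20, 20))
  r <- nct_paired(coh, fast_cfg(), iterations = 200, seed = 6)
  expect_lt(r$p_edges["s1--s2"], 0.05)
  expect_lt(r$p_structure, 0.05)
})
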