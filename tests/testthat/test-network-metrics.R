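test_that("three-node path centralities match the hand computation", {
  W <- wmat(3, list(list(1, 2, 0.5), list(2, 3, 0.25)),
            nodes = c("a", "b", "c"))
  ct <- centralities(W)
  expect_equal(ct$strength, c(0.5, 0.75, 0.25))
  # distances: d(a,b) = 2, d(b,c) = 4, d(a,c) = 6
  expect_equal(ct$closeness, c(1 / 8, 1 / 6, 1 / 10))
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(mean(ct$z_strength), 0, tolerance = 1e-12)
  expect_equal(sd(ct$z_strength), 1, tolerance = 1e-12)
})

test_that("symmetric triangles give identical indices and zero z-scores", {
  W <- wmat(3, list(list(1, 2, 0.3), list(2, 3, 0.3), list(1, 3, 0.3)))
  ct <- centralities(W)
  expect_equal(length(unique(ct$strength)), 1)
  expect_equal(ct$z_strength, rep(0, 3))
  expect_equal(ct$z_closeness, rep(0, 3))
  expect_equal(ct$z_betweenness, rep(0, 3))
})

test_that("negative weights contribute absolute values to strength and distance", {
  W <- wmat(2, list(list(1, 2, -0.3)))
  ct <- centralities(W)
  expect_equal(ct$strength, c(0.3, 0.3))
  expect_equal(ct$closeness, c(0.3, 0.3))  # 1 / (1/0.3)
})

test_that("empty networks yield all-zero centralities and disconnection gives closeness 0", {
  W <- matrix(0, 3, 3)
  ct <- centralities(W)
  expect_equal(ct$strength, rep(0, 3))
  expect_equal(ct$closeness, rep(0, 3))
  expect_equal(ct$betweenness, rep(0, 3))

  # one isolated node
  W2 <- wmat(3, list(list(1, 2, 0.5)))
  ct2 <- centralities(W2)
  expect_equal(ct2$closeness[3], 0)
})

test_that("modularity matches hand values and the igraph oracle", {
  # all-in-one community is exactly 0
  W <- wmat(4, list(list(1, 2, 0.7), list(3, 4, 0.2), list(2, 3, 0.1)))
  expect_equal(modularity_q(W, rep(1, 4)), 0)

  # two disjoint unit edges split into their pairs: Q = 0.5 exactly
  W2 <- wmat(4, list(list(1, 2, 1), list(3, 4, 1)))
  expect_equal(modularity_q(W2, c(1, 1, 2, 2)), 0.5)

  # igraph cross-check on a random weighted graph
  set.seed(16)
  W3 <- matrix(0, 6, 6)
  W3[upper.tri(W3)] <- runif(15) * (runif(15) < 0.6)
  W3 <- W3 + t(W3)
  memb <- sample(1:3, 6, replace = TRUE)
  g <- igraph::graph_from_adjacency_matrix(W3, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(modularity_q(W3, memb),
               igraph::modularity(g, memb, weights = igraph::E(g)$weight),
               tolerance = 1e-12)

  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "empty network")
})

test_that("planted partitions score higher than arbitrary ones", {
  W <- matrix(0.05, 8, 8); diag(W) <- 0
  W[1:4, 1:4] <- 0.4; W[5:8, 5:8] <- 0.4; diag(W) <- 0
  planted <- rep(1:2, each = 4)
  expect_gt(modularity_q(W, planted), modularity_q(W, rep(1:2, 4)))
})

test_that("community detection recovers planted structure and reports Q consistently", {
  W <- matrix(0.05, 8, 8)
  W[1:4, 1:4] <- 0.4; W[5:8, 5:8] <- 0.4; diag(W) <- 0
  cp <- detect_communities(W, seed = 2)
  expect_equal(length(unique(cp$membership)), 2)
  expect_equal(length(unique(cp$membership[1:4])), 1)
  expect_equal(length(unique(cp$membership[5:8])), 1)
  expect_equal(cp$Q, modularity_q(W, cp$membership), tolerance = 1e-12)
})

test_that("two disjoint cliques are separated with the closed-form Q", {
  edges <- list()
  for (i in 1:2) for (j in (i + 1):3) edges <- c(edges, list(list(i, j, 1)))
  for (i in 4:5) for (j in (i + 1):6) edges <- c(edges, list(list(i, j, 1)))
  W <- wmat(6, edges)
  cp <- detect_communities(W, seed = 3)
  expect_equal(length(unique(cp$membership)), 2)
  # each community holds half the weight: Q = 1 - 2 * (1/2)^2 = 0.5
  expect_equal(cp$Q, 0.5, tolerance = 1e-12)
})

test_that("uniform complete graphs are flagged as weak structure", {
  W <- matrix(0.3, 6, 6); diag(W) <- 0
  cp <- detect_communities(W, seed = 4)
  expect_lt(cp$Q, 0.05)
  expect_true(cp$weak)
})

test_that("detected Q equals the exhaustive maximum on small graphs", {
  set.seed(17)
  for (rep in 1:3) {
    W <- matrix(0, 6, 6)
    W[upper.tri(W)] <- round(runif(15) * (runif(15) < 0.5), 2)
    W <- W + t(W)
    if (sum(W) == 0) next
    cp <- detect_communities(W, seed = rep)
    expect_equal(cp$Q, exhaustive_best_modularity(W), tolerance = 1e-10)
  }
})

test_that("strength ranking is invariant to positive rescaling", {
  set.seed(18)
  W <- matrix(0, 7, 7)
  W[upper.tri(W)] <- runif(21, -0.3, 0.5)
  W <- W + t(W)
  r1 <- rank(centralities(W)$strength)
  r2 <- rank(centralities(3.7 * W)$strength)
  expect_equal(r1, r2)
})

test_that("detection is deterministic under a fixed seed", {
  set.seed(19)
  W <- matrix(0, 10, 10)
  W[upper.tri(W)] <- runif(45, 0, 0.4) * (runif(45) < 0.4)
  W <- W + t(W)
  expect_identical(detect_communities(W, seed = 7),
                   detect_communities(W, seed = 7))
})
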