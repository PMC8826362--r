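test_that("precision spec honours density, SPD and determinism", {
  # empty graph
  s0 <- make_precision_spec(3, 0)
  expect_true(all(s0$true_pcor[upper.tri(s0$true_pcor)] == 0))

  # requested support density (rounding may move it by one edge)
  s <- make_precision_spec(15, 0.7, seed = 1)
  ne <- sum(s$true_pcor[upper.tri(s$true_pcor)] != 0)
  expect_true(ne %in% c(73, 74))

  # SPD by construction
  ev <- eigen(s$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_true(all(abs(s$true_pcor) < 1))

  # same seed twice is bitwise identical
  expect_identical(make_precision_spec(12, 0.3, seed = 42),
                   make_precision_spec(12, 0.3, seed = 42))

  expect_error(make_precision_spec(15, 1.2), "density")
  expect_error(make_precision_spec(1, 0.5), "p")
})

test_that("true_pcor agrees with partial correlations of the implied covariance", {
  s <- make_precision_spec(10, 0.4, seed = 5)
  Sigma <- solve(s$precision)
  K <- solve(Sigma)  # round trip
  d <- sqrt(diag(K))
  pc <- -K / tcrossprod(d)
  diag(pc) <- 0
  expect_lt(max(abs(pc - s$true_pcor)), 1e-10)
  # zero pattern of pcor equals off-diagonal zero pattern of precision
  off <- upper.tri(K)
  expect_identical(s$true_pcor[off] == 0, s$precision[off] == 0)
})

test_that("edge-list precision specs are SPD with the requested support", {
  edges <- data.frame(node_i = c("a", "b"), node_j = c("b", "c"),
                      pcor = c(0.4, -0.2))
  sp <- precision_spec_from_edges(c("a", "b", "c"), edges)
  ev <- eigen(sp$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(sp$true_pcor["a", "c"], 0)
  expect_gt(sp$true_pcor["a", "b"], 0)
  expect_lt(sp$true_pcor["b", "c"], 0)
  expect_error(precision_spec_from_edges(c("a", "b"), data.frame(
    node_i = "a", node_j = "z", pcor = 0.1)), "unknown node")

  # the reference 15-node structure: SPD hub network with gQoL well connected
  ref <- default_precision_spec()
  Sig <- solve(ref$precision)
  R <- Sig / tcrossprod(sqrt(diag(Sig)))
  expect_gt(sum(R["gQoL", -1] > 0.3), 8)
  expect_equal(max(abs(ref$true_pcor)), 0.36, tolerance = 0.05)
})

test_that("cohort margins match their targets and discretisation contract", {
  spec <- make_precision_spec(3, 0.5, seed = 2)
  defs <- list(
    scale_definition("gQoL", "continuous", mean = 69.9, sd = 19.0),
    scale_definition("fatigue", "continuous", mean = 72.6, sd = 18.6),
    scale_definition("insomnia", "ordinal", levels = 4L)
  )
  coh <- generate_cohort(spec, defs, n = 50000, missing_rate = 0, seed = 9)
  g <- coh$scores$M0[, "gQoL"]
  # clipping at 0/100 slightly biases the clipped-normal margin; 0.5 covers it
  expect_lt(abs(mean(g) - 69.9), 0.5)
  expect_lt(abs(sd(g) - 19.0), 0.5)

  ins <- coh$scores$M0[, "insomnia"]
  expect_true(all(vapply(ins, function(v) {
    any(abs(v - c(0, 100 / 3, 200 / 3, 100)) < 1e-9)
  }, logical(1))))

  # no-missing contract
  expect_false(any(coh$miss$M0) || any(coh$miss$M12))
})

test_that("latent structure and pairing behave as specified", {
  spec <- make_precision_spec(5, 0.5, seed = 3)
  defs <- lapply(sprintf("s%d", 1:5), scale_definition, kind = "continuous")
  coh <- generate_cohort(spec, defs, n = 100000, missing_rate = 0, seed = 4,
                         subject_corr = 0.5, keep_latent = TRUE)
  Z <- attr(coh, "latent")
  Sigma <- solve(spec$precision)
  Sigma <- Sigma / tcrossprod(sqrt(diag(Sigma)))
  expect_lt(max(abs(cor(Z[, , 1]) - Sigma)), 0.02)
  expect_lt(max(abs(cor(Z[, , 2]) - Sigma)), 0.02)
  # cross-time latent correlation per coordinate
  cc <- vapply(1:5, function(k) cor(Z[, k, 1], Z[, k, 2]), numeric(1))
  expect_lt(max(abs(cc - 0.5)), 0.02)
})

test_that("missingness is MCAR and never hits both visits of a scale", {
  spec <- make_precision_spec(4, 0.5, seed = 6)
  defs <- lapply(sprintf("s%d", 1:4), scale_definition, kind = "continuous")
  coh <- generate_cohort(spec, defs, n = 20000, missing_rate = 0.08,
                         seed = 11, keep_latent = TRUE)
  Z <- attr(coh, "latent")
  for (k in 1:4) {
    m <- as.numeric(coh$miss$M0[, k])
    fit <- summary(lm(m ~ Z[, k, 1]))
    expect_lt(abs(fit$coefficients[2, "t value"]), 3)
  }
  both <- coh$miss$M0 & coh$miss$M12
  expect_false(any(both))
  expect_lt(abs(mean(coh$miss$M0) - 0.08), 0.01)
})

test_that("per-subject streams: enlarging n keeps earlier subjects' draws", {
  spec <- make_precision_spec(4, 0.5, seed = 6)
  defs <- lapply(sprintf("s%d", 1:4), scale_definition, kind = "continuous")
  small <- generate_cohort(spec, defs, n = 40, seed = 5)
  big <- generate_cohort(spec, defs, n = 80, seed = 5)
  expect_identical(small$scores$M0, big$scores$M0[1:40, ])
  expect_identical(small$miss$M12, big$miss$M12[1:40, ])
})
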