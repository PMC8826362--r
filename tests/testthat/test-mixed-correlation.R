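test_that("variable classification uses the strict 7-level rule", {
  expect_equal(classify_variable(rep(c(0, 100 / 3, 200 / 3, 100), 10)),
               "ordinal")
  expect_equal(classify_variable(seq_len(50)), "continuous")
  expect_equal(classify_variable(rep(1:7, 5)), "continuous")
  expect_equal(classify_variable(rep(1:6, 5)), "ordinal")
  expect_error(classify_variable(rep(3, 10)), "constant")
})

test_that("polychoric matches the 2x2 median-split closed form", {
  # P(both < 0) = 1/4 + asin(rho)/(2*pi), so rho = sin(2*pi*(P - 1/4))
  expect_lt(abs(polychoric(matrix(c(40, 10, 10, 40), 2)) - sin(0.3 * pi)),
            1e-3)
  expect_lt(abs(polychoric(matrix(c(25, 25, 25, 25), 2))), 1e-3)
  # another median-split table: P = 0.30 -> rho = sin(0.1*pi)
  expect_lt(abs(polychoric(matrix(c(30, 20, 20, 30), 2)) - sin(0.1 * pi)),
            1e-3)
  # negative association
  expect_lt(abs(polychoric(matrix(c(10, 40, 40, 10), 2)) + sin(0.3 * pi)),
            1e-3)
  expect_error(polychoric(matrix(c(50, 50, 0, 0), 2, byrow = TRUE)),
               "degenerate")
})

test_that("polychoric recovers a latent correlation from discretised data", {
  set.seed(6)
  n <- 2000
  rho <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  qs <- qnorm(c(0.25, 0.5, 0.75))
  xo <- findInterval(x, qs)
  yo <- findInterval(y, qs)
  expect_lt(abs(polychoric(xo, yo) - rho), 0.05)
})

test_that("polyserial behaves at the null, the identity limit and in between", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  y_ind <- findInterval(rnorm(n), qnorm(c(0.3, 0.6)))
  expect_lt(abs(polyserial(x, y_ind)), 0.05)

  y_self <- as.integer(x > 0)
  expect_warning(r_self <- polyserial(x, y_self), "boundary")
  expect_gt(r_self, 0.95)

  rho <- 0.6
  z <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  y5 <- findInterval(z, qnorm(c(0.2, 0.4, 0.6, 0.8)))
  expect_lt(abs(polyserial(x, y5) - rho), 0.05)
})

test_that("continuous-only input reduces exactly to the Pearson matrix", {
  set.seed(8)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  mm <- mixed_matrix(X)
  expect_lt(max(abs(mm$R - cor(X))), 1e-12)
  expect_true(all(mm$method_labels[upper.tri(mm$method_labels)] == "pearson"))
  expect_false(mm$pd_repaired)

  # 2 x 2 is always PD
  mm2 <- mixed_matrix(X[, 1:2])
  expect_false(mm2$pd_repaired)
})

test_that("method dispatch picks polyserial/polychoric for ordinal columns", {
  set.seed(9)
  n <- 400
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  X <- cbind(cont = z1 * 10 + 50,
             ord1 = findInterval(z2, qnorm(c(0.3, 0.7))),
             ord2 = findInterval(rnorm(n), qnorm(c(0.25, 0.5, 0.75))))
  mm <- mixed_matrix(X)
  expect_equal(mm$method_labels["cont", "ord1"], "polyserial")
  expect_equal(mm$method_labels["ord1", "ord2"], "polychoric")
  expect_equal(mm$method_labels["cont", "cont"], "")
  expect_lt(abs(mm$R["cont", "ord1"] - 0.5), 0.1)
})

test_that("PD repair clips eigenvalues and stays near the Higham projection", {
  R <- matrix(c(1, 0.9, -0.3,
                0.9, 1, 0.6,
                -0.3, 0.6, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 0)  # genuinely indefinite input
  out <- nearest_pd_correlation(R)
  expect_true(out$repaired)
  expect_lt(out$min_eigenvalue_before, 0)
  expect_gt(out$max_change, 0)
  ev2 <- eigen(out$R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev2), -1e-12)
  expect_equal(diag(out$R), rep(1, 3))
  # alternating-projections oracle
  hig <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  expect_lt(max(abs(out$R - hig)), 0.05)

  # no-op on an already-PD matrix
  good <- random_corr(4, seed = 2)
  out2 <- nearest_pd_correlation(good)
  expect_false(out2$repaired)
  expect_identical(out2$R, good)
})
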