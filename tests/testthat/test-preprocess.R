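two_tp <- function(m0, m12, range = c(0, 100)) {
  make_test_cohort(M0 = m0, M12 = m12, range = range)
}

test_that("scale reversal reflects about the pivot and is an involution", {
  m0 <- cbind(dep = c(0, 10, 39), pain = c(16.67, 50, 100))
  m12 <- cbind(dep = c(39, 20, 5), pain = c(0, 25, 83.33))
  coh <- make_test_cohort(M0 = m0, M12 = m12, range = c(0, 100))
  coh$scale_defs[[1]]$range <- c(0, 39)
  rules <- data.frame(scale = c("dep", "pain"), pivot = c(39, 100))

  rev1 <- reverse_scales(coh, rules)
  expect_equal(rev1$scores$M0[1, "dep"], 39, ignore_attr = TRUE)
  expect_equal(rev1$scores$M0[1, "pain"], 83.33, ignore_attr = TRUE)
  expect_equal(rev1$scale_defs[[1]]$direction, "higher_worse")

  rev2 <- reverse_scales(rev1, rules)
  expect_equal(rev2$scores$M0, coh$scores$M0)
  expect_equal(rev2$scores$M12, coh$scores$M12)

  expect_error(reverse_scales(coh, data.frame(scale = "nope", pivot = 100)),
               "unknown scale")
})

test_that("reversal flips Spearman correlation signs but not magnitudes", {
  set.seed(1)
  x <- rnorm(60, 50, 10)
  y <- 0.8 * x + rnorm(60, 10, 5)
  coh <- two_tp(cbind(a = x, b = y), cbind(a = x, b = y))
  rev1 <- reverse_scales(coh, data.frame(scale = "b", pivot = 100))
  r0 <- cor(x, y, method = "spearman")
  r1 <- cor(rev1$scores$M0[, "a"], rev1$scores$M0[, "b"],
            method = "spearman")
  expect_equal(r1, -r0)
})

test_that("copyMean reproduces the trailing-gap closed form", {
  # population means: M0 = (10+30+20)/3 = 20, M12 = (24+24)/2 = 24
  m0 <- cbind(s = c(10, 30, 20))
  m12 <- cbind(s = c(NA, 24, 24))
  coh <- two_tp(m0, m12)
  imp <- impute_copy_mean(coh)
  expect_equal(imp$scores$M12[1, "s"], 14, ignore_attr = TRUE)  # 10 + (24 - 20)
  expect_false(any(imp$miss$M12))
  log <- attr(imp, "imputation_log")
  expect_equal(log$rule, "trailing")
})

test_that("copyMean interior gaps follow interpolation plus mean-shape shift", {
  # popmeans: t1 (10+30)/2 = 20, t2 only 26 observed, t3 (20+28)/2 = 24
  scores <- list(
    T1 = cbind(s = c(10, 30)),
    T2 = cbind(s = c(NA, 26)),
    T3 = cbind(s = c(20, 28))
  )
  defs <- list(scale_definition("s", "continuous"))
  coh <- cohort_table(scores, scale_defs = defs, subjects = c("a", "b"))
  imp <- impute_copy_mean(coh)
  # subject linear interp 15, popmean linear interp 22, shift 26 - 22 = 4
  expect_equal(imp$scores$T2[1, "s"], 19, ignore_attr = TRUE)
})

test_that("copyMean is idempotent and a no-op on complete data", {
  set.seed(2)
  m0 <- cbind(a = runif(30, 20, 80), b = runif(30, 20, 80))
  m12 <- m0 + 5
  coh <- two_tp(m0, m12)
  expect_equal(impute_copy_mean(coh)$scores, coh$scores)

  coh$scores$M0[c(3, 7), "a"] <- NA
  coh$scores$M12[c(5, 9), "b"] <- NA
  coh$miss <- lapply(coh$scores, is.na)
  once <- impute_copy_mean(coh)
  twice <- impute_copy_mean(once)
  expect_identical(once$scores, twice$scores)
})

test_that("copyMean clips to range and snaps ordinal scales to their grid", {
  m0 <- cbind(s = c(98, 60, 70))
  m12 <- cbind(s = c(NA, 90, 100))
  coh <- two_tp(m0, m12)
  imp_clip <- impute_copy_mean(coh)
  expect_lte(imp_clip$scores$M12[1, "s"], 100)
  imp_raw <- impute_copy_mean(coh, clip = FALSE)
  # 98 + (95 - 76) = 117 overflows the 0-100 range without clipping
  expect_gt(imp_raw$scores$M12[1, "s"], 100)

  m0o <- cbind(o = c(100 / 3, 0, 100))
  m12o <- cbind(o = c(NA, 100 / 3, 200 / 3))
  coho <- make_test_cohort(M0 = m0o, M12 = m12o, kinds = "ordinal")
  impo <- impute_copy_mean(coho)
  grid <- c(0, 100 / 3, 200 / 3, 100)
  expect_true(min(abs(impo$scores$M12[1, "o"] - grid)) < 1e-9)
})

test_that("copyMean errors when a timepoint has no observations of a scale", {
  m0 <- cbind(s = c(10, 20))
  m12 <- cbind(s = c(NA_real_, NA_real_))
  coh <- two_tp(m0, m12)
  expect_error(impute_copy_mean(coh), "population mean undefined")
})

test_that("missing_summary reports fractions and all-missing subjects", {
  m0 <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  m12 <- cbind(a = c(1, NA, 3), b = c(4, NA, 6))
  full <- two_tp(m0, cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
  ms <- missing_summary(full)
  expect_equal(ms$missing_fraction, c(0, 0))
  expect_equal(ms$subjects_all_missing, c(0, 0))

  part <- two_tp(m0, m12)
  ms2 <- missing_summary(part)
  expect_equal(ms2$missing_fraction[2], 2 / 6)
  expect_equal(ms2$subjects_all_missing[2], 1)
})

test_that("generated missingness fraction is recovered by the summary", {
  spec <- make_precision_spec(5, 0.4, seed = 8)
  defs <- lapply(sprintf("s%d", 1:5), scale_definition, kind = "continuous")
  coh <- generate_cohort(spec, defs, n = 487, missing_rate = 0.04, seed = 21)
  ms <- missing_summary(coh)
  expect_true(all(abs(ms$missing_fraction - 0.04) < 0.01))
})
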