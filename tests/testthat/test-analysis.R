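test_that("relative difference reproduces the published rounding", {
  expect_equal(round(relative_difference(1.65, 1.72), 2), -0.04)
  expect_equal(round(relative_difference(4.37, 3.53), 2), 0.24)
  expect_equal(relative_difference(3.3, 3.3), 0)
  expect_equal(relative_difference(c(2, 3), c(4, 2)), c(-0.5, 0.5))
  expect_error(relative_difference(1, 0), "nonzero")
})

test_that("exact signed-rank test matches base R when ties are absent", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(6:18, 1)
    x <- round(rnorm(n), 6)          # continuous: no ties, no zeros
    y <- round(rnorm(n), 6)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("signed-rank handles zeros, ties and degenerate input", {
  # antithetic pairs: statistic sits at the null mean, p = 1
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(0.5, -0.5, 0.5, -0.5, 0.5, -0.5)
  res <- wilcoxon_signed_rank(x, y)
  n <- 6
  expect_equal(unname(res$statistic), n * (n + 1) / 4)
  expect_equal(res$p.value, 1)

  # a large uniform shift is maximally significant
  z <- rnorm(15)
  res <- wilcoxon_signed_rank(z + 5, z)
  expect_lt(res$p.value, 0.01)
  expect_equal(res$p.value, 2 / 2^15, tolerance = 1e-12)

  # zero differences are dropped
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(1, 2, 3, 4.5, 4.2, 6.8, 6.1)
  expect_equal(wilcoxon_signed_rank(x, y)$n, 4)
  expect_error(wilcoxon_signed_rank(x, x), "degenerate")
  expect_error(wilcoxon_signed_rank(1:4, 2:5), "at least 5")

  # normal approximation stays close to exact for moderate n
  set.seed(4)
  a <- rnorm(19)
  b <- a + rnorm(19, 0.4, 0.6)
  pe <- wilcoxon_signed_rank(a, b)$p.value
  pn <- wilcoxon_signed_rank(a, b, method = "normal")$p.value
  expect_equal(pn, pe, tolerance = 0.15)
})

test_that("exact signed-rank on the cohort's LCA-rest columns gives ~0.020", {
  d <- cohort_cbf()
  p <- wilcoxon_signed_rank(d$lca_rest_insilico, d$lca_rest_invivo)$p.value
  expect_equal(p, 0.0199, tolerance = 1e-3)
})

test_that("Spearman correlation is rank-based and transform-invariant", {
  set.seed(9)
  x <- rexp(25)
  y <- x + rnorm(25, 0, 0.3)
  rho <- spearman_rho(x, y)
  expect_equal(rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(spearman_rho(exp(x), y), rho, tolerance = 1e-12)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Bland-Altman uses bias +/- 1.96 sd and is translation-equivariant", {
  set.seed(3)
  x <- rnorm(15, 5)
  y <- rnorm(15, 5)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  ba2 <- bland_altman(x + 0.7, y)
  expect_equal(ba2$bias, ba$bias + 0.7)
  expect_equal(ba2$loa_lower, ba$loa_lower + 0.7)
  expect_equal(ba2$loa_upper, ba$loa_upper + 0.7)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_lower, ba0$loa_upper), c(0, 0, 0))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("flow split sums to 100% and matches the worked example", {
  fs <- flow_split(1.72, 0.75)
  expect_equal(round(fs[["left"]], 1), 69.6)
  expect_equal(round(fs[["right"]], 1), 30.4)
  expect_equal(sum(flow_split(0.37, 2.9)), 100, tolerance = 1e-12)
  expect_equal(unname(flow_split(2, 2)), c(50, 50))
  expect_error(flow_split(0, 1), "> 0")
})

test_that("cohort_summary handles degenerate input", {
  s <- cohort_summary(7)
  expect_equal(s$median, 7)
  expect_equal(s$iqr, 0)
  expect_error(cohort_summary(numeric(0)), "empty")
})

test_that("cohort_validation reproduces the published agreement statistics", {
  cv <- cohort_validation(cohort_cbf_long())
  lr <- cv$agreement[["left.rest"]]
  expect_equal(lr$n, 19)
  expect_equal(round(lr$spearman_rho, 4), 0.9482)
  expect_equal(round(lr$bias, 2), -0.10)
  expect_equal(lr$reldiff$median, -0.04)
  rh <- cv$agreement[["right.hyperemia"]]
  expect_equal(round(rh$bias, 2), 0.31)
  expect_equal(round(rh$loa_upper, 2), 1.45)
  fs <- cv$flow_split[["rest.invivo"]]
  expect_equal(round(fs$median), 57)
  expect_output(print(cv), "flow split")
})
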