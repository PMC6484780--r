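test_that("size factors reproduce median-of-ratios behaviour", {
  m <- cbind(c(5, 10, 20), c(5, 10, 20))
  expect_equal(size_factors(m), c(1, 1))

  m2 <- rbind(g1 = c(2, 4), g2 = c(8, 16))
  expect_equal(size_factors(m2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  m3 <- cbind(c(3, 7, 11), 3 * c(3, 7, 11))
  f <- size_factors(m3)
  expect_equal(f[2] / f[1], 3)

  expect_error(size_factors(matrix(0, 3, 2)), "all-zero")
})

test_that("size factors scale with proportional column multipliers", {
  set.seed(11)
  for (i in 1:20) {
    base <- rpois(30, 50) + 1
    mult <- sample(1:5, 4, replace = TRUE)
    m <- sapply(mult, function(k) k * base)
    f <- size_factors(m)
    expect_equal(f / f[1], mult / mult[1], tolerance = 1e-12)
  }
})

test_that("vst is a monotone log transform anchored at zero", {
  expect_equal(vst(0, 1), 0)
  expect_equal(vst(7, 1), 3)
  expect_equal(vst(7, 2), log2(4.5))
  v <- vst(0:100, 1)
  expect_true(all(diff(v) > 0))
  expect_error(vst(5, 0), "positive")
})

test_that("NB two-group test recovers planted fold changes and degenerates safely", {
  a <- matrix(rep(c(4, 6, 5), each = 2), nrow = 1)
  expect_equal(nb_two_group_test(a, a)$log2fc, 0)

  z <- matrix(0, 5, 3)
  res0 <- nb_two_group_test(z, z)
  expect_equal(res0$log2fc, rep(0, 5))
  expect_equal(res0$pvalue, rep(1, 5))

  expect_error(nb_two_group_test(matrix(1, 2, 1), matrix(1, 2, 3)),
               "2 samples")

  set.seed(101)
  mu <- 2^runif(500, 5, 9)
  a <- matrix(rnbinom(500 * 6, mu = 4 * mu, size = 10), 500)
  b <- matrix(rnbinom(500 * 6, mu = mu, size = 10), 500)
  res <- nb_two_group_test(a, b)
  expect_lt(abs(mean(res$log2fc) - 2), 0.3)
})

test_that("NB test type-I error is calibrated on null NB data", {
  set.seed(2024)
  mu <- 2^runif(2000, 5, 9)
  a <- matrix(rnbinom(2000 * 6, mu = mu, size = 10), 2000)
  b <- matrix(rnbinom(2000 * 6, mu = mu, size = 10), 2000)
  rate <- mean(nb_two_group_test(a, b)$pvalue < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("NB test agrees with DESeq2 on a shared fixture", {
  set.seed(77)
  mu <- 2^runif(300, 5, 9)
  mu2 <- mu
  mu2[1:30] <- mu[1:30] / 3
  a <- matrix(rnbinom(300 * 5, mu = mu2, size = 10), 300,
              dimnames = list(sprintf("g%03d", 1:300), NULL))
  b <- matrix(rnbinom(300 * 5, mu = mu, size = 10), 300,
              dimnames = list(sprintf("g%03d", 1:300), NULL))
  mine <- nb_two_group_test(a, b)

  suppressMessages(library(DESeq2))
  cond <- factor(rep(c("kd", "ctrl"), each = 5), levels = c("ctrl", "kd"))
  dds <- suppressMessages(DESeqDataSetFromMatrix(
    cbind(a, b), S4Vectors::DataFrame(cond = cond), ~cond))
  res <- results(suppressMessages(DESeq(dds, quiet = TRUE)))
  expect_gt(cor(mine$log2fc, res$log2FoldChange, use = "complete.obs"), 0.99)
  # both engines flag the majority of the planted 3-fold genes
  expect_gt(sum(bh_fdr(mine$pvalue)[1:30] < 0.05), 20)
})

test_that("BH adjustment equals an independent step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(9)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("BH output never falls below the raw p value", {
  set.seed(10)
  p <- runif(200)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("rank-sum exact branch matches full enumeration", {
  expect_equal(rank_sum_test(c(2, 2, 3), c(2, 2, 3))$pvalue, 1)

  r <- rank_sum_test(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$pvalue, 0.1)

  expect_error(rank_sum_test(numeric(0), 1), "non-empty")

  set.seed(21)
  for (i in 1:100) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- sample(0:5, n, replace = TRUE)  # ties likely
    y <- sample(0:5, m, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$pvalue, oracle_ranksum(x, y))
  }
})

test_that("rank-sum large-sample branch behaves like the tie-corrected normal test", {
  set.seed(22)
  x <- rnorm(10); y <- rnorm(10) + 2
  p <- rank_sum_test(x, y)$pvalue
  ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE)$p.value)
  expect_equal(p, ref, tolerance = 0.02)
  # identical large samples: no evidence
  expect_gt(rank_sum_test(rnorm(10), rnorm(10))$pvalue, 0.05)
})

test_that("Welch test matches the textbook formulas", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$pvalue, 1)

  set.seed(31)
  x <- rnorm(6, sd = 2); y <- rnorm(6, sd = 2)
  mine <- welch_t_test(x, y)
  ref <- oracle_welch(x, y)
  expect_equal(mine$t, ref$t, tolerance = 1e-10)
  expect_equal(mine$df, ref$df, tolerance = 1e-10)
  expect_equal(mine$pvalue, ref$pvalue, tolerance = 1e-10)

  m2 <- welch_t_test(c(0, 0, 0, 1), c(10, 10, 10, 11))
  r2 <- oracle_welch(c(0, 0, 0, 1), c(10, 10, 10, 11))
  expect_equal(m2$pvalue, r2$pvalue, tolerance = 1e-6)

  # equal variances and n: Welch t equals the pooled Student statistic
  x <- c(1, 4, 6, 9); y <- c(2, 5, 7, 10)
  sp <- sqrt((var(x) + var(y)) / 2)
  expect_equal(welch_t_test(x, y)$t,
               (mean(x) - mean(y)) / (sp * sqrt(2 / 4)))

  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Pearson correlation handles exact and undefined cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- c(2, 1, 4, 5)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), manual)
  expect_true(is.na(pearson_correlation(c(1, 1, 1), y[1:3])))
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("geometric mean is exact and guards against non-positive input", {
  expect_equal(geometric_mean(c(4, 4, 4)), 4)
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(c(2, 8, 4)), 4)
  expect_error(geometric_mean(c(2, 0, 4)), "positive")
  expect_equal(geometric_mean(c(2, -1, 8), floor = 2), geometric_mean(c(2, 2, 8)))
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  expect_equal(hypergeom_enrichment(0, 3, 4, 10), 1)
  expect_equal(hypergeom_enrichment(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_enrichment(5, 10, 5, 10), 1)  # n = N saturation
  expect_error(hypergeom_enrichment(5, 4, 5, 10), "inconsistent")

  set.seed(41)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeom_enrichment(k, n, K, N), oracle_hypergeom(k, n, K, N))
  }
})
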