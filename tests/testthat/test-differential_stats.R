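test_that("moderated t is zero when group means coincide", {
  set.seed(41)
  half <- matrix(rnorm(20 * 5), 20, 5)
  X <- cbind(half, half) # both groups see identical data
  dimnames(X) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10))
  tab <- moderatedT(X, rep(c("A", "B"), each = 5))
  expect_true(all(tab$t == 0))
  expect_true(all(tab$p == 1))
})

test_that("prior df 0 reduces to the ordinary pooled t", {
  set.seed(42)
  X <- matrix(rnorm(200 * 16, 5), 200, 16,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:16)))
  labels <- rep(c("A", "B"), each = 8)
  tab <- moderatedT(X, labels, priorDf = 0)
  tOracle <- oracle_pooled_t(X, labels == "A", labels == "B")
  expect_lt(max(abs(tab$t - tOracle)), 1e-9)
})

test_that("hyperparameter fit agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(43)
  X <- matrix(rnorm(500 * 12, 5, sqrt(rchisq(500, 4) / 4)), 500, 12,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:12)))
  labels <- rep(c("A", "B"), each = 6)
  tab <- moderatedT(X, labels)
  design <- model.matrix(~ factor(labels))
  fit <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(attr(tab, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(tab, "s02"), fit$s2.prior, tolerance = 0.05)
  expect_gt(cor(abs(tab$t), abs(fit$t[, 2])), 0.9999)
})

test_that("planted shifts are detected with controlled size", {
  set.seed(44)
  nG <- 1000; nShift <- 50; n <- 30
  X <- matrix(rnorm(nG * 2 * n, 5), nG, 2 * n,
              dimnames = list(sprintf("g%04d", 1:nG),
                              sprintf("s%02d", 1:(2 * n))))
  X[1:nShift, 1:n] <- X[1:nShift, 1:n] + 1.5
  tab <- moderatedT(X, rep(c("A", "B"), each = n))
  shifted <- tab$p[1:nShift]
  nulls <- tab$p[(nShift + 1):nG]
  expect_gte(mean(shifted < 0.05), 0.90)
  expect_lte(mean(nulls < 0.05), 0.07)
})

test_that("moderated t p-values are uniform under the null", {
  set.seed(45)
  X <- matrix(rnorm(5000 * 12, 5), 5000, 12,
              dimnames = list(sprintf("g%04d", 1:5000), sprintf("s%02d", 1:12)))
  tab <- moderatedT(X, rep(c("A", "B"), each = 6))
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  set.seed(46)
  p <- runif(100)^2
  expect_equal(bhAdjust(p), oracle_bh(p))
  # permutation invariance (up to the same permutation)
  perm <- sample(100)
  expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank tests behave on forced and enumerated cases", {
  expect_gt(rankTests(rep(1:5, 2), rep(c("A", "B"), each = 5),
                      "wilcoxon2")$p, 0.99)
  # complete separation: W equals its enumerated extreme
  w <- rankTests(c(1, 2, 3, 10, 11, 12), rep(c("A", "B"), each = 3),
                 "wilcoxon2")
  expect_equal(w$statistic, 0) # no y precedes any x
  expect_error(rankTests(1:3, c("A", "A", "A"), "wilcoxon2"), "2 groups")
})

test_that("kruskal-wallis type-I error is controlled", {
  set.seed(47)
  rej <- vapply(1:1000, function(i) {
    v <- rnorm(30)
    rankTests(v, rep(c("A", "B", "C"), each = 10), "kruskal")$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("chi-square matches hand arithmetic and rejects zero marginals", {
  flat <- chiSquare(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  tab <- matrix(c(20, 5, 5, 20), 2)
  # all expected counts are 12.5; sum((O - E)^2 / E) = 4 * 7.5^2 / 12.5
  expect_equal(chiSquare(tab)$statistic, 4 * 7.5^2 / 12.5)
  expect_error(chiSquare(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("chi-square size is near nominal under independence", {
  set.seed(48)
  rej <- vapply(1:1000, function(i) {
    x <- sample(c("a", "b"), 80, replace = TRUE)
    y <- sample(c("u", "v"), 80, replace = TRUE)
    tab <- table(x, y)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA)
    chiSquare(tab)$p < 0.05
  }, TRUE)
  rate <- mean(rej, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("spearman correlation equals rank-then-Pearson with ties", {
  x <- 1:10
  expect_equal(spearmanCor(x, x^3)$rho, 1)
  expect_equal(spearmanCor(x, rev(x))$rho, -1)
  set.seed(49)
  a <- sample(1:5, 50, replace = TRUE)
  b <- a + sample(0:3, 50, replace = TRUE)
  expect_lt(abs(spearmanCor(a, b)$rho - cor(a, b, method = "spearman")),
            1e-12)
  expect_lt(abs(spearmanCor(a, b)$rho - cor(rank(a), rank(b))), 1e-12)
  expect_error(spearmanCor(rep(1, 5), 1:5), "constant")
})

test_that("ddCT arithmetic is exact", {
  expect_equal(ddct(20, 18, 22, 18), 4)
  expect_equal(ddct(20, 20, 20, 20), 1)
  expect_equal(ddct(25, 20, 25, 20), 1)
  expect_error(ddct(NA, 1, 1, 1), "finite")
})
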