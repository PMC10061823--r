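test_that("prognostic screen keeps a strong gene and controls the null rate", {
  kept <- vapply(1:10, function(i) {
    set.seed(710 + i)
    n <- 500
    g <- rnorm(n)
    times <- rexp(n, 0.005 * exp(1 * g))
    cens <- runif(n, 0, 800)
    m <- rbind(RISKY = g, NOISE = rnorm(n))
    colnames(m) <- sprintf("s%03d", 1:n)
    x <- M7GExperiment(m, unit = "log2_tpm1")
    clin <- data.frame(sample_id = colnames(m),
                       os_time = pmax(pmin(times, cens), 1),
                       os_event = as.integer(times <= cens))
    sc <- suppressWarnings(prognosticScreen(x, clin, c("RISKY", "NOISE")))
    sc$kept[sc$gene == "RISKY"] && sc$HR[sc$gene == "RISKY"] > 1
  }, TRUE)
  expect_gte(mean(kept), 0.95)

  # pure-noise retention near the nominal level
  set.seed(72)
  n <- 500; nG <- 1000
  m <- matrix(rnorm(nG * n), nG, n,
              dimnames = list(sprintf("g%04d", 1:nG), sprintf("s%03d", 1:n)))
  times <- rexp(n, 0.005)
  cens <- runif(n, 0, 800)
  clin <- data.frame(sample_id = colnames(m),
                     os_time = pmax(pmin(times, cens), 1),
                     os_event = as.integer(times <= cens))
  x <- M7GExperiment(m, unit = "log2_tpm1")
  sc <- prognosticScreen(x, clin, rownames(m))
  expect_gte(mean(sc$kept), 0.03)
  expect_lte(mean(sc$kept), 0.07)

  expect_error(prognosticScreen(x, clin, c("ABSENT1", "ABSENT2")),
               "disjoint")
})

test_that("the score is the PC1 + PC2 projection with risk-oriented signs", {
  set.seed(73)
  X <- matrix(rnorm(40 * 60, 5), 40, 60,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:60)))
  hr <- setNames(runif(40, 0.5, 2), rownames(X))
  sr <- m7gScore(X, hr)
  # oracle: eigendecomposition of the sample covariance with the same rule
  Z <- t(scale(t(X)))
  eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  proj <- t(Z) %*% eig$vectors[, 1:2]
  risk <- hr > 1
  for (j in 1:2) {
    if (sum(eig$vectors[risk, j]) < 0) proj[, j] <- -proj[, j]
  }
  expect_lt(max(abs(sampleScores(sr) - (proj[, 1] + proj[, 2]))), 1e-8)
})

test_that("the score is invariant to gene order and per-gene constants", {
  set.seed(74)
  X <- matrix(rnorm(20 * 30, 5), 20, 30,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30)))
  hr <- setNames(runif(20, 0.5, 2), rownames(X))
  base <- sampleScores(m7gScore(X, hr))
  perm <- sample(20)
  expect_equal(sampleScores(m7gScore(X[perm, ], hr[perm])), base,
               tolerance = 1e-9)
  shifted <- X + matrix(rnorm(20, 0, 5), 20, 30)
  expect_equal(sampleScores(m7gScore(shifted, hr)), base, tolerance = 1e-9)
})

test_that("rank-1 expression collapses the score to the first component", {
  g <- rnorm(30)
  X <- outer(seq(0.5, 2, length.out = 6), g)
  dimnames(X) <- list(paste0("g", 1:6), paste0("s", 1:30))
  hr <- setNames(rep(2, 6), rownames(X))
  sr <- m7gScore(X, hr)
  emb <- pcaEmbed(X, r = 2)
  expect_lt(max(abs(abs(sampleScores(sr)) - abs(emb@scores[, 1]))), 1e-8)
})

test_that("high-score groups carry worse survival and the score tracks the latent risk", {
  rhos <- numeric(10)
  for (i in 1:10) {
    cfg <- m7gConfig(cohortSizes = c(one = 400), nBackground = 60,
                     nPhenotype = 40, nImmune = 10, nStromal = 10,
                     beta = 0.9, delta = 1.5, batchShift = c(one = 0))
    sim <- simulateMetaCohort(cfg, seed = 750 + i)
    lg <- logNormalize(sim$expr)
    al <- alignSamples(lg, sim$clinical)
    phg <- grep("^PHG", rownames(al$expr), value = TRUE)
    scr <- suppressWarnings(prognosticScreen(al$expr, al$clinical, phg))
    sr <- m7gScore(al$expr[attr(scr, "kept"), ], setNames(scr$HR, scr$gene))
    truth <- sim$truth[match(names(sampleScores(sr)), sim$truth$sample_id), ]
    rhos[i] <- spearmanCor(sampleScores(sr), truth$L)$rho
    if (i == 1) {
      sr <- stratify(sr, al$clinical$os_time, al$clinical$os_event)
      expect_lt(sr@logrank$p, 0.001)
      # direction: high group dies faster (lower KM tail)
      expect_lt(min(sr@logrank$km$high$surv), min(sr@logrank$km$low$surv))
    }
  }
  expect_true(all(rhos > 0))
  expect_gte(mean(rhos), 0.8)
})

test_that("stratify rejects constant scores and flags null replication", {
  times <- rexp(50, 0.01); events <- rbinom(50, 1, 0.8)
  expect_error(stratify(setNames(rep(1, 50), paste0("s", 1:50)),
                        times, events),
               "distinct")
})

test_that("score-response association detects the planted logit link", {
  hits <- vapply(1:10, function(i) {
    cfg <- m7gConfig(cohortSizes = c(one = 300), nBackground = 20,
                     nPhenotype = 10, nImmune = 5, nStromal = 5,
                     responseSlope = 1.5, batchShift = c(one = 0))
    sim <- simulateMetaCohort(cfg, seed = 760 + i)
    score <- sim$truth$L # latent risk stands in for the fitted score
    grp <- ifelse(score > median(score), "high", "low")
    ra <- responseAssociation(score, grp, sim$clinical$response)
    ra$wilcoxon$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("response p-values are uniform when response is shuffled", {
  set.seed(77)
  score <- rnorm(200)
  grp <- ifelse(score > 0, "high", "low")
  ps <- vapply(1:500, function(i) {
    resp <- sample(c("CR", "PR", "SD", "PD"), 200, replace = TRUE)
    responseAssociation(score, grp, resp)$wilcoxon$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("degenerate response tables raise errors", {
  score <- rnorm(20)
  grp <- rep("high", 20) # zero marginal for the low group
  resp <- rep(c("CR", "SD"), 10)
  expect_error(responseAssociation(score, grp, resp), "marginal")
  expect_error(responseAssociation(score, grp, rep("CR", 20)), ">= 2")
})

test_that("crosstabs quantify agreement and score differences", {
  a <- rep(c("A", "B"), each = 50)
  xt <- scoreGroupCrosstab(a, a)
  expect_true(all(xt$table[row(xt$table) != col(xt$table)] == 0))
  expect_equal(xt$cramersV, 1, tolerance = 1e-12)

  set.seed(78)
  b <- sample(c("X", "Y", "Z"), 3000, replace = TRUE)
  c2 <- sample(c("U", "V"), 3000, replace = TRUE)
  expect_lt(scoreGroupCrosstab(c2, b)$cramersV, 0.1)
  expect_error(scoreGroupCrosstab(a, a[-1]), "unequal")

  # planted: pattern-B-derived cluster carries the higher score
  sim <- shared_sim()$sim
  truth <- sim$truth
  xt2 <- scoreGroupCrosstab(truth$pattern, truth$gene_cluster, truth$L)
  expect_lt(xt2$kruskal$p, 0.01)
  medians <- tapply(truth$L, truth$gene_cluster, median)
  expect_equal(names(which.max(medians)), "C")
})
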