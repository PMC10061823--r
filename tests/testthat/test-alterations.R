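test_that("mutation frequency reproduces the cohort arithmetic", {
  cohort <- sprintf("s%03d", 1:505)
  mut <- data.frame(sample_id = cohort[1:5], gene = "EIF4G3",
                    variant_classification = "Missense_Mutation",
                    is_nonsynonymous = TRUE)
  mf <- mutationFrequency(mut, cohort, m7gRegulators())
  expect_equal(round(mf$overall$frequency_pct, 2), 0.99)
  expect_equal(mf$perGene$n_mutated[mf$perGene$gene == "EIF4G3"], 5)

  none <- mutationFrequency(mut[0, ], cohort, m7gRegulators())
  expect_true(all(none$perGene$frequency_pct == 0))
  expect_equal(none$overall$frequency_pct, 0)

  all5 <- mutationFrequency(
    data.frame(sample_id = cohort, gene = "WDR4",
               variant_classification = "Missense_Mutation",
               is_nonsynonymous = TRUE),
    cohort, "WDR4")
  expect_equal(all5$perGene$frequency_pct, 100)
  expect_error(mutationFrequency(mut, cohort, character()), "empty gene")
})

test_that("silent records never count as mutated", {
  cohort <- paste0("s", 1:10)
  mut <- data.frame(sample_id = c("s1", "s2"), gene = "EIF4E",
                    variant_classification = c("Missense_Mutation", "Silent"),
                    is_nonsynonymous = c(TRUE, FALSE))
  mf <- mutationFrequency(mut, cohort, "EIF4E")
  expect_equal(mf$perGene$n_mutated, 1)
  expect_equal(unname(tmb(mut, cohort)[c("s1", "s2")]), c(1 / 38, 0))
})

test_that("CNV frequencies match a brute-force tally", {
  cohort <- sprintf("s%03d", 1:505)
  cnv <- data.frame(sample_id = cohort[1:101], gene = "AGO2", state = "gain")
  cf <- cnvFrequency(cnv, cohort, "AGO2")
  expect_equal(cf$gain_pct, 20.0)
  expect_equal(cf$loss_pct, 0)

  set.seed(81)
  rcnv <- data.frame(sample_id = sample(cohort, 400, replace = TRUE),
                     gene = sample(c("A", "B", "C"), 400, replace = TRUE),
                     state = sample(c("gain", "loss", "neutral"), 400,
                                    replace = TRUE))
  rcnv <- rcnv[!duplicated(rcnv[, 1:2]), ]
  cf2 <- cnvFrequency(rcnv, cohort, c("A", "B", "C"))
  for (g in c("A", "B", "C")) {
    expect_equal(cf2$gain_pct[cf2$gene == g],
                 100 * sum(rcnv$gene == g & rcnv$state == "gain") / 505)
  }
  expect_error(cnvFrequency(data.frame(sample_id = "s001", gene = "A",
                                       state = "amp"), cohort, "A"),
               "vocabulary")
})

test_that("co-mutation detects perfect co-occurrence and matches Fisher enumeration", {
  cohort <- paste0("s", 1:8)
  mut <- data.frame(sample_id = rep(c("s1", "s2", "s3"), 2),
                    gene = rep(c("G1", "G2"), each = 3),
                    variant_classification = "Missense_Mutation",
                    is_nonsynonymous = TRUE)
  cm <- coMutation(mut, c("G1", "G2"), cohort)
  expect_equal(cm$phi, 1)
  expect_lt(cm$p, 0.05)

  # hand-sized table: package Fisher p equals full enumeration
  set.seed(82)
  m2 <- data.frame(sample_id = c("s1", "s2", "s5", "s1", "s3"),
                   gene = c("G1", "G1", "G1", "G2", "G2"),
                   variant_classification = "Missense_Mutation",
                   is_nonsynonymous = TRUE)
  cm2 <- coMutation(m2, c("G1", "G2"), cohort)
  x <- cohort %in% c("s1", "s2", "s5")
  y <- cohort %in% c("s1", "s3")
  tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)), 2)
  expect_equal(cm2$p, oracle_fisher2x2(tab), tolerance = 1e-12)

  expect_message(cm3 <- coMutation(m2, c("G1", "G2", "NEVER"), cohort),
                 "NEVER")
  expect_identical(attr(cm3, "skipped"), "NEVER")
})

test_that("co-mutation p-values are uniform for independent genes", {
  set.seed(83)
  cohort <- paste0("s", 1:50)
  ps <- vapply(1:1000, function(i) {
    g1 <- sample(cohort, 15)
    g2 <- sample(cohort, 15)
    mut <- data.frame(sample_id = c(g1, g2),
                      gene = rep(c("A", "B"), c(length(g1), length(g2))),
                      variant_classification = "Missense_Mutation",
                      is_nonsynonymous = TRUE)
    coMutation(mut, c("A", "B"), cohort)$p
  }, numeric(1))
  # Fisher p is conservative and discrete; check super-uniformity only
  expect_lte(mean(ps <= 0.05), 0.07)
  expect_gte(mean(ps <= 0.5), 0.25)
})

test_that("TMB arithmetic, absence handling and additivity hold", {
  cohort <- c("s1", "s2", "s3")
  mut <- data.frame(sample_id = c("s1", "s1", "s1", "s2"),
                    gene = c("A", "B", "C", "A"),
                    variant_classification = c(rep("Missense_Mutation", 3),
                                               "Silent"),
                    is_nonsynonymous = c(TRUE, TRUE, TRUE, FALSE))
  b <- tmb(mut, cohort)
  expect_equal(unname(b), c(3 / 38, 0, 0))
  expect_error(tmb(mut, cohort, exomeMb = 0), "> 0")

  other <- data.frame(sample_id = "s1", gene = "D",
                      variant_classification = "Nonsense_Mutation",
                      is_nonsynonymous = TRUE)
  expect_equal(tmb(rbind(mut, other), cohort)["s1"],
               tmb(mut, cohort)["s1"] + tmb(other, cohort)["s1"])
})

test_that("planted Poisson burden separates the two patterns", {
  cfg <- m7gConfig(cohortSizes = c(one = 200), nBackground = 20,
                   nPhenotype = 10, nImmune = 5, nStromal = 5,
                   mutMeanLow = 5, mutMeanHigh = 20, batchShift = c(one = 0))
  sim <- simulateMetaCohort(cfg, seed = 84)
  burden <- tmb(sim$mutations, sim$truth$sample_id)
  w <- rankTests(burden, sim$truth$pattern, "wilcoxon2")
  expect_lt(w$p, 0.001)
  medians <- tapply(burden, sim$truth$pattern, median)
  expect_gt(medians[["B"]], medians[["A"]])
})
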