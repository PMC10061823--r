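test_that("product-limit estimates match hand enumeration", {
  km <- kmFit(c(10, 12, 15, 20), c(1, 0, 0, 0), truncateYears = NULL)
  expect_equal(km$all$surv[km$all$time == 10], 0.75)

  allCens <- kmFit(c(5, 8, 13), c(0, 0, 0), truncateYears = NULL)
  expect_true(all(allCens$all$surv == 1))

  set.seed(61)
  times <- rexp(80, 1 / 100)
  events <- rbinom(80, 1, 0.7)
  km2 <- kmFit(times, events, truncateYears = NULL)$all
  orc <- oracle_km(times, events)
  got <- km2$surv[km2$n.event > 0]
  expect_lt(max(abs(got - orc$surv)), 1e-12)
})

test_that("follow-up truncation censors beyond the horizon", {
  km <- kmFit(c(300, 5000), c(1, 1), truncateYears = 10)$all
  expect_true(all(km$time <= 10 * 365.25))
  expect_equal(sum(km$n.event), 1) # the late event became censored
})

test_that("log-rank agrees with risk-set enumeration and is order-invariant", {
  t0 <- c(1, 2, 3, 4, 5, 6)
  e0 <- rep(1, 6)
  g0 <- rep(c("A", "B"), each = 3)
  lr <- logrankTest(t0, e0, g0)
  expect_equal(lr$statistic, oracle_logrank(t0, e0, g0), tolerance = 1e-9)

  same <- logrankTest(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                      rep(c("A", "B"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  set.seed(62)
  times <- rexp(60, 1 / 50); events <- rbinom(60, 1, 0.8)
  grp <- sample(c("A", "B"), 60, replace = TRUE)
  perm <- sample(60)
  a <- logrankTest(times, events, grp)
  b <- logrankTest(times[perm], events[perm], grp[perm])
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_error(logrankTest(c(1, 2), c(0, 0), c("A", "B")), "event")
})

test_that("log-rank size is near nominal under exchangeability", {
  set.seed(63)
  rej <- vapply(1:1000, function(i) {
    times <- rexp(40, 1 / 50)
    events <- rbinom(40, 1, 0.8)
    grp <- rep(c("A", "B"), each = 20)
    logrankTest(times, events, grp)$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Cox fit recovers a planted log hazard ratio of log(2)", {
  betas <- vapply(1:10, function(i) {
    set.seed(640 + i)
    x <- rbinom(2000, 1, 0.5)
    times <- rexp(2000, 0.01 * exp(log(2) * x))
    cens <- runif(2000, 0, 300)
    coxFit(pmin(times, cens), as.integer(times <= cens),
           data.frame(x = x))$beta
  }, numeric(1))
  expect_gte(mean(betas), 0.61)
  expect_lte(mean(betas), 0.78)
})

test_that("Cox fit is well calibrated under the null", {
  ok <- vapply(1:10, function(i) {
    set.seed(650 + i)
    x <- rnorm(2000)
    times <- rexp(2000, 0.01)
    cens <- runif(2000, 0, 300)
    fit <- coxFit(pmin(times, cens), as.integer(times <= cens),
                  data.frame(x = x))
    abs(fit$beta) < 0.1 && fit$p > 0.05
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("duplicating the dataset keeps beta and shrinks the SE by sqrt(2)", {
  set.seed(66)
  x <- rnorm(300)
  times <- rexp(300, 0.01 * exp(0.5 * x))
  events <- rep(1L, 300)
  one <- coxFit(times, events, data.frame(x = x), ties = "breslow")
  two <- coxFit(rep(times, 2), rep(events, 2),
                data.frame(x = rep(x, 2)), ties = "breslow")
  expect_equal(two$beta, one$beta, tolerance = 1e-6)
  expect_equal(two$se / one$se, 1 / sqrt(2), tolerance = 1e-3)
})

test_that("Cox fit rejects degenerate designs", {
  expect_error(coxFit(1:10, rep(1, 10), data.frame(x = rep(2, 10))),
               "constant")
  expect_error(coxFit(1:3, c(1, 1, 1),
                      data.frame(a = rnorm(3), b = rnorm(3), c = rnorm(3))),
               "more subjects")
})

test_that("cutpoint scan recovers a planted hazard switch near zero", {
  cuts <- vapply(1:10, function(i) {
    set.seed(670 + i)
    score <- runif(500, -1, 1)
    times <- rexp(500, 0.005 * exp(log(3) * (score > 0)))
    cens <- runif(500, 0, 600)
    cp <- survCutpoint(pmin(times, cens), as.integer(times <= cens), score)
    cp@cutoff
  }, numeric(1))
  expect_lt(abs(mean(cuts)), 0.15)
  expect_gte(mean(abs(cuts) <= 0.15), 0.7)
})

test_that("cutpoint respects minprop and equals the squared log-rank at a split", {
  set.seed(68)
  score <- rnorm(100)
  times <- rexp(100, 0.01)
  events <- rbinom(100, 1, 0.8)
  cp <- survCutpoint(times, events, score, minprop = 0.2)
  expect_gte(min(cp@groupSizes), ceiling(0.2 * 100))
  # standardized statistic squared == survdiff chi-square at the same split
  z <- cp@statistics$z[cp@statistics$cutpoint == cp@cutoff]
  lr <- logrankTest(times, events, score > cp@cutoff)
  expect_equal(z^2, lr$statistic, tolerance = 1e-9)
  expect_error(survCutpoint(times[1:9], events[1:9], score[1:9]), ">= 10")
  expect_error(survCutpoint(times, events, rep(1, 100)), "distinct")
})

test_that("null cutpoints do not replicate out of sample", {
  replicatedP <- vapply(1:20, function(i) {
    set.seed(690 + i)
    score <- rnorm(150)
    times <- rexp(150, 0.01)
    cens <- runif(150, 0, 300)
    ot <- pmin(times, cens); oe <- as.integer(times <= cens)
    cp <- survCutpoint(ot, oe, score)
    # independent replicate with the same null structure
    score2 <- rnorm(150)
    t2 <- rexp(150, 0.01); c2 <- runif(150, 0, 300)
    logrankTest(pmin(t2, c2), as.integer(t2 <= c2), score2 > cp@cutoff)$p
  }, numeric(1))
  expect_gte(mean(replicatedP > 0.05), 0.85)
})
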