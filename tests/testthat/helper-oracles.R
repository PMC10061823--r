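# Independent brute-force oracles used to validate the implementation.
# Each one is written against the statistic's definition, not the package's
# code path.

# ssGSEA: literal double loop over the definition -- genes ordered by
# decreasing expression, weighted in-set ECDF minus unweighted out-of-set
# ECDF, summed over all positions.
oracle_ssgsea <- function(X, set, alpha) {
  vapply(seq_len(ncol(X)), function(j) {
    r <- rank(X[, j])
    ord <- order(X[, j], decreasing = TRUE)
    genes <- rownames(X)[ord]
    rOrd <- r[ord]
    inSet <- genes %in% set
    wSum <- sum(abs(rOrd[inSet])^alpha)
    nOut <- sum(!inSet)
    es <- 0
    pin <- 0
    pout <- 0
    for (i in seq_along(genes)) {
      if (inSet[i]) pin <- pin + abs(rOrd[i])^alpha / wSum
      else pout <- pout + 1 / nOut
      es <- es + (pin - pout)
    }
    es
  }, numeric(1))
}

# Product-limit estimator by explicit risk-set enumeration.
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    atRisk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Two-group log-rank by risk-set enumeration (chi-square form).
oracle_logrank <- function(times, events, group) {
  g <- as.integer(factor(group)) == 1
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (tt in ts) {
    n <- sum(times >= tt)
    n1 <- sum(times >= tt & g)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & g)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Fisher exact two-sided p for a 2x2 table by full hypergeometric
# enumeration (two-sided: sum of all table probabilities <= observed).
oracle_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Pooled ordinary two-sample t per gene.
oracle_pooled_t <- function(X, i1, i2) {
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(X[, i1, drop = FALSE])
  m2 <- rowMeans(X[, i2, drop = FALSE])
  v1 <- apply(X[, i1, drop = FALSE], 1, var)
  v2 <- apply(X[, i2, drop = FALSE], 1, var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
}
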