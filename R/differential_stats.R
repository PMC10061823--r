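#' Moderated t-test between two expression patterns
#'
#' Empirical-Bayes moderated two-sample t: per-gene pooled variances are
#' shrunk toward a common prior variance fitted by method of moments on the
#' scaled-F distribution of the sample variances (trigamma inversion), and
#' the t-statistic gains the prior degrees of freedom. With `priorDf = 0`
#' the statistic reduces to the ordinary pooled two-sample t.
#'
#' @param expr an [M7GExperiment-class] or genes x samples matrix
#'   (log scale).
#' @param labels two-group factor/character vector over the samples.
#' @param priorDf optional forced prior degrees of freedom d0 (`NULL`
#'   estimates it; `0` disables moderation; `Inf` fully pools).
#' @return A `DegTable` data.frame: one row per gene with group means,
#'   log2 fold change, moderated t, raw and BH-adjusted p, and posterior
#'   variance; the fitted hyperparameters are in
#'   `attr(x, "d0")` / `attr(x, "s02")`.
#' @export
moderatedT <- function(expr, labels, priorDf = NULL) {
  X <- if (is(expr, "M7GExperiment")) exprValues(expr) else as.matrix(expr)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(X))
  grp <- sort(unique(labels))
  if (length(grp) != 2) stop("moderatedT needs exactly two groups")
  i1 <- labels == grp[1]
  i2 <- labels == grp[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  m1 <- rowMeans(X[, i1, drop = FALSE])
  m2 <- rowMeans(X[, i2, drop = FALSE])
  v1 <- rowSums((X[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (all(s2 == 0)) stop("all genes have zero variance")

  if (is.null(priorDf)) {
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(dg / 2) + log(dg / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigammaInverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    d0 <- priorDf
    s02 <- if (d0 > 0) mean(s2[s2 > 0]) else 0
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, (m1 - m2) / se, 0)
  df <- d0 + dg
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[se == 0] <- 1
  out <- data.frame(gene = rownames(X), mean1 = m1, mean2 = m2,
                    logFC = m1 - m2, t = tstat, p = p,
                    padj = bhAdjust(p), s2post = s2post,
                    row.names = NULL)
  attr(out, "groups") <- grp
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; errors on p-values outside
#' `[0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Rank-based group comparison tests
#'
#' Two-sided Wilcoxon rank-sum (normal approximation with continuity and tie
#' correction) or Kruskal-Wallis, as used for two- and three-group score
#' comparisons.
#'
#' @param values numeric vector.
#' @param labels group labels (exactly 2 groups for `wilcoxon2`, >= 2 for
#'   `kruskal`).
#' @param kind `"wilcoxon2"` or `"kruskal"`.
#' @return List with `statistic` and `p`.
#' @export
rankTests <- function(values, labels, kind = c("wilcoxon2", "kruskal")) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  groups <- split(values, labels)
  if (any(lengths(groups) == 0)) stop("a group is empty")
  if (kind == "wilcoxon2") {
    if (length(groups) != 2) stop("wilcoxon2 needs exactly 2 groups")
    ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                              exact = FALSE, correct = TRUE))
  } else {
    if (length(groups) < 2) stop("kruskal needs >= 2 groups")
    ht <- stats::kruskal.test(values, factor(labels))
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson chi-square with `(r - 1)(c - 1)` degrees of freedom;
#' a zero row or column marginal is an error.
#'
#' @param tab two-way contingency table (matrix of counts).
#' @return List with `statistic`, `df`, `p`.
#' @export
chiSquare <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks, with the t-approximation
#' p-value on `n - 2` degrees of freedom. A constant input vector is an
#' error (rho undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Relative expression by the 2^(-ddCT) method
#'
#' Quantifies qPCR relative expression: `ddCT = (target - reference) -
#' (control_target - control_reference)` and the result is `2^(-ddCT)`.
#'
#' @param targetCt,referenceCt CT values in the condition of interest.
#' @param controlTargetCt,controlReferenceCt CT values in the calibrator.
#' @return Relative expression (numeric).
#' @examples
#' ddct(20, 18, 22, 18) # 4.0
#' @export
ddct <- function(targetCt, referenceCt, controlTargetCt, controlReferenceCt) {
  vals <- c(targetCt, referenceCt, controlTargetCt, controlReferenceCt)
  if (any(!is.finite(vals))) stop("all CT values must be finite")
  ddctVal <- (targetCt - referenceCt) - (controlTargetCt - controlReferenceCt)
  2^(-ddctVal)
}
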