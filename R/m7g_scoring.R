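# The core construction: univariate prognostic screening of phenotype genes,
# the PCA-based per-sample m7G score, survival stratification, and the
# score-response / score-cluster association reports.

#' Univariate prognostic screen of candidate genes
#'
#' Fits a univariate Cox model of overall survival on each candidate gene's
#' expression and keeps genes with Wald p below `alpha`, recording the
#' hazard-ratio direction of every kept gene.
#'
#' @param expr an [M7GExperiment-class] (log scale).
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`
#'   aligned to `expr` (see [alignSamples()]).
#' @param candidates character vector of genes to screen (must overlap the
#'   matrix).
#' @param alpha Wald p threshold (default 0.05).
#' @return data.frame with one row per screened gene (`gene`, `beta`, `HR`,
#'   `p`, `kept`); the kept gene list is `attr(x, "kept")`.
#' @export
prognosticScreen <- function(expr, clinical, candidates, alpha = 0.05) {
  if (!length(candidates)) stop("empty candidate list")
  present <- intersect(candidates, rownames(expr))
  if (!length(present)) stop("candidate list disjoint from matrix")
  X <- exprValues(expr)[present, , drop = FALSE]
  clin <- clinical[match(colnames(expr), clinical$sample_id), ]
  if (anyNA(clin$sample_id)) stop("clinical table missing aligned samples")
  rows <- lapply(present, function(g) {
    v <- X[g, ]
    if (stats::sd(v) == 0)
      return(data.frame(gene = g, beta = NA_real_, HR = NA_real_,
                        p = NA_real_))
    fit <- coxFit(clin$os_time, clin$os_event, data.frame(x = v))
    data.frame(gene = g, beta = fit$beta, HR = fit$HR, p = fit$p)
  })
  out <- do.call(rbind, rows)
  out$kept <- !is.na(out$p) & out$p < alpha
  if (!any(out$kept))
    warning("no candidate gene passed the prognostic screen")
  attr(out, "kept") <- out$gene[out$kept]
  attr(out, "alpha") <- alpha
  out
}

#' PCA-based m7G score
#'
#' Genes are z-scored and decomposed by SVD; each sample's score is its
#' projection on principal component 1 plus its projection on component 2.
#' Components are sign-oriented so the summed loadings over risk genes
#' (hazard ratio > 1) are non-negative, making high score mean high risk;
#' when no risk genes exist the orientation makes the summed loadings over
#' protective genes non-positive.
#'
#' @param expr an [M7GExperiment-class] or matrix restricted to the score
#'   genes (>= 2 non-degenerate genes, >= 3 samples).
#' @param hrDirections named numeric vector of per-gene hazard ratios from
#'   [prognosticScreen()] (names must cover the genes used).
#' @return A [ScoreResult-class] without cutoff/groups (see [stratify()]).
#' @export
m7gScore <- function(expr, hrDirections) {
  X <- if (is(expr, "M7GExperiment")) exprValues(expr) else as.matrix(expr)
  if (ncol(X) < 3) stop("need >= 3 samples")
  sds <- rowSds(X)
  if (sum(sds > 0) < 2) stop("fewer than 2 non-degenerate genes")
  if (any(sds == 0)) X <- X[sds > 0, , drop = FALSE]
  genes <- rownames(X)
  hr <- hrDirections[genes]
  if (anyNA(hr)) stop("hrDirections must name every score gene")
  Z <- t(rowZscore(X)) # samples x genes
  sv <- svd(Z, nu = 2, nv = 2)
  loadings <- sv$v
  proj <- sv$u %*% diag(sv$d[1:2], 2)
  orientation <- numeric(2)
  risk <- hr > 1
  for (j in 1:2) {
    s <- if (any(risk)) sum(loadings[risk, j]) else -sum(loadings[!risk, j])
    orientation[j] <- if (s >= 0) 1 else -1
    loadings[, j] <- orientation[j] * loadings[, j]
    proj[, j] <- orientation[j] * proj[, j]
  }
  dimnames(loadings) <- list(genes, c("PC1", "PC2"))
  score <- stats::setNames(proj[, 1] + proj[, 2], colnames(X))
  new("ScoreResult", score = score, genes = genes, loadings = loadings,
      orientation = orientation, hrDirection = stats::setNames(as.numeric(hr),
                                                               genes),
      cutoff = NA_real_, group = character(), logrank = list())
}

#' Stratify samples by the maximally selected score cutoff
#'
#' Finds the optimal survival cutoff of the m7G score ([survCutpoint()]),
#' attaches high/low group labels (high = score strictly above the cutoff),
#' and reports the two-group log-rank test and KM curves of the split.
#'
#' @param score a [ScoreResult-class] or named numeric score vector.
#' @param times,events survival data aligned to the score order.
#' @param minprop minimum group proportion for the cutpoint scan.
#' @param truncateYears follow-up horizon (years) for the reported KM/log-rank.
#' @return A [ScoreResult-class] with `cutoff`, `group` and `logrank` filled
#'   (the log-rank list also carries the KM curves).
#' @export
stratify <- function(score, times, events, minprop = 0.1,
                     truncateYears = 10) {
  sr <- if (is(score, "ScoreResult")) score else
    new("ScoreResult", score = score,
        genes = character(), loadings = matrix(0, 0, 2),
        orientation = c(1, 1), hrDirection = numeric(),
        cutoff = NA_real_, group = character(), logrank = list())
  s <- sampleScores(sr)
  cp <- survCutpoint(times, events, s, minprop = minprop)
  grp <- stats::setNames(ifelse(s > cp@cutoff, "high", "low"), names(s))
  lr <- logrankTest(times, events, grp, truncateYears = truncateYears)
  km <- kmFit(times, events, grp, truncateYears = truncateYears)
  sr@cutoff <- cp@cutoff
  sr@group <- grp
  sr@logrank <- list(statistic = lr$statistic, p = lr$p, km = km,
                     cutpoint = cp)
  validObject(sr)
  sr
}

#' Score-response association report
#'
#' Compares the m7G score between therapy responders (CR/PR) and
#' non-responders (SD/PD) with a two-sided Wilcoxon test, and tests the
#' score-group by response-class contingency table with a chi-square test.
#'
#' @param scores numeric per-sample scores.
#' @param groups high/low labels per sample.
#' @param response RECIST labels per sample (`CR`, `PR`, `SD`, `PD`;
#'   other/missing values are dropped).
#' @return List with `wilcoxon` (statistic, p), `table` (2x2 counts),
#'   `chisq` (statistic, p), and `responderClass` per sample.
#' @export
responseAssociation <- function(scores, groups, response) {
  stopifnot(length(scores) == length(response),
            length(groups) == length(response))
  cls <- ifelse(response %in% c("CR", "PR"), "CR/PR",
                ifelse(response %in% c("SD", "PD"), "SD/PD", NA))
  keep <- !is.na(cls)
  cls <- cls[keep]
  scores <- scores[keep]
  groups <- groups[keep]
  if (any(table(factor(cls, levels = c("CR/PR", "SD/PD"))) < 2))
    stop("each response class needs >= 2 samples")
  w <- rankTests(scores, cls, "wilcoxon2")
  tab <- table(group = groups, response = cls)
  if (nrow(tab) < 2)
    stop("zero marginal: all samples fall in one score group")
  cs <- chiSquare(tab)
  list(wilcoxon = w, table = tab, chisq = cs, responderClass = cls)
}

#' Cross-tabulate two sample groupings
#'
#' Contingency table of two assignments over the same samples (e.g. m7G
#' cluster vs gene cluster, or cluster vs score group), with Cramer's V
#' agreement; when scores are supplied a Kruskal-Wallis test of the score
#' across the second assignment's labels is added.
#'
#' @param a,b label vectors of equal length.
#' @param scores optional numeric per-sample scores.
#' @return List with `table`, `cramersV`, and optionally `kruskal`.
#' @export
scoreGroupCrosstab <- function(a, b, scores = NULL) {
  if (length(a) != length(b)) stop("label vectors of unequal length")
  tab <- table(a, b)
  n <- sum(tab)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(cs$statistic) / (n * (min(dim(tab)) - 1)))
  out <- list(table = tab, cramersV = v)
  if (!is.null(scores)) {
    if (length(scores) != length(b)) stop("scores length mismatch")
    out$kruskal <- rankTests(scores, b, "kruskal")
  }
  out
}
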