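# Resampling-based consensus clustering with CDF / delta-area / PAC model
# selection. Base clusterer: agglomerative, average linkage, distance
# 1 - Pearson correlation between sample profiles; only samples are
# resampled.

.consensusCdf <- function(M) {
  v <- sort(M[upper.tri(M)])
  grid <- seq(0, 1, by = 0.01)
  cdf <- stats::ecdf(v)(grid)
  data.frame(value = grid, cdf = cdf)
}

.areaUnderCdf <- function(cdf) {
  # trapezoid-free histogram area as in the consensus-clustering literature
  sum(diff(cdf$value) * cdf$cdf[-1])
}

#' Consensus clustering of sample profiles
#'
#' For each candidate `k`, `reps` subsamples of `ceiling(pItem * n)` samples
#' are clustered (hierarchical, average linkage, 1 - Pearson distance
#' between sample columns) and the consensus matrix records, for every
#' sample pair, the fraction of co-sampled replicates in which the pair
#' co-clustered (0 when never co-sampled). The final assignment at each `k`
#' cuts an average-linkage tree of `1 - M_k` into `k` groups. Model
#' selection reports the consensus CDF, area under the CDF `A(k)`, relative
#' delta area, and PAC (proportion of consensus entries in (0.1, 0.9));
#' the chosen `k` minimizes PAC unless overridden.
#'
#' @param expr an [M7GExperiment-class] restricted to the feature set of
#'   interest (e.g. the regulator genes), or a numeric genes x samples
#'   matrix.
#' @param kRange candidate cluster counts (subset of `2:(n-1)`).
#' @param reps number of resampling replicates (>= 1).
#' @param pItem sample subsampling proportion in (0, 1].
#' @param seed integer seed controlling the resampling.
#' @param kOverride optional manual choice of `k` (must be in `kRange`);
#'   mirrors choosing `k` by CDF inspection.
#' @return A [ConsensusResult-class].
#' @examples
#' x <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
#' cc <- consensusCluster(x, kRange = 2:3, reps = 20, seed = 1)
#' chosenK(cc)
#' @export
consensusCluster <- function(expr, kRange = 2:9, reps = 1000, pItem = 0.8,
                             seed = 1L, kOverride = NULL) {
  X <- if (is(expr, "M7GExperiment")) exprValues(expr) else as.matrix(expr)
  n <- ncol(X)
  if (nrow(X) < 2) stop("consensus clustering needs >= 2 genes")
  if (!(pItem > 0 && pItem <= 1)) stop("pItem must lie in (0, 1]")
  if (reps < 1) stop("reps must be >= 1")
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2 || max(kRange) > n - 1)
    stop("kRange outside [2, n - 1]")
  if (n < max(kRange) * 3)
    stop("need at least 3 * max(kRange) samples")
  D <- 1 - suppressWarnings(stats::cor(X))
  if (anyNA(D)) stop("degenerate profile matrix")
  diag(D) <- 0

  m <- ceiling(pItem * n)
  nK <- length(kRange)
  num <- lapply(seq_len(nK), function(i) matrix(0, n, n))
  den <- matrix(0, n, n)
  withSeed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m))
      ind <- numeric(n)
      ind[idx] <- 1
      den <- den + tcrossprod(ind)
      h <- stats::hclust(stats::as.dist(D[idx, idx]), method = "average")
      for (i in seq_len(nK)) {
        cl <- stats::cutree(h, kRange[i])
        for (c in unique(cl)) {
          v <- numeric(n)
          v[idx[cl == c]] <- 1
          num[[i]] <- num[[i]] + tcrossprod(v)
        }
      }
    }
  })

  sampled <- diag(den) > 0
  consensus <- lapply(num, function(Nm) {
    M <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
    pos <- den > 0
    M[pos] <- Nm[pos] / den[pos]
    diag(M)[sampled] <- 1
    M
  })
  names(consensus) <- paste0("k", kRange)

  assignments <- matrix(NA_integer_, n, nK,
                        dimnames = list(colnames(X), paste0("k", kRange)))
  cdfs <- vector("list", nK)
  names(cdfs) <- paste0("k", kRange)
  A <- pac <- numeric(nK)
  for (i in seq_len(nK)) {
    M <- consensus[[i]]
    hf <- stats::hclust(stats::as.dist(1 - M), method = "average")
    assignments[, i] <- stats::cutree(hf, kRange[i])
    cdfs[[i]] <- .consensusCdf(M)
    A[i] <- .areaUnderCdf(cdfs[[i]])
    off <- M[upper.tri(M)]
    pac[i] <- mean(off > 0.1 & off < 0.9)
  }
  delta <- c(A[1], diff(A) / A[-nK])
  # minimize PAC; exact ties resolve toward the larger k (any merge of
  # stable clusters is itself stable, so the finest stable k is informative)
  chosen <- if (!is.null(kOverride)) {
    if (!kOverride %in% kRange) stop("kOverride must be inside kRange")
    as.integer(kOverride)
  } else max(kRange[pac <= min(pac) + 1e-12])

  new("ConsensusResult", consensus = consensus, assignments = assignments,
      cdf = cdfs, areaUnderCdf = stats::setNames(A, paste0("k", kRange)),
      deltaArea = stats::setNames(delta, paste0("k", kRange)),
      pac = stats::setNames(pac, paste0("k", kRange)),
      chosenK = chosen, kRange = kRange, reps = as.integer(reps),
      pItem = pItem, seed = as.integer(seed))
}

#' PCA embedding of sample profiles
#'
#' Genes are z-scored (rows centered and scaled; zero-variance genes are
#' excluded with a warning), the embedding comes from the singular value
#' decomposition, and each component is oriented so its largest-magnitude
#' loading is positive.
#'
#' @param expr an [M7GExperiment-class] or genes x samples matrix.
#' @param r number of components, `<= min(genes, samples)`.
#' @return A [PcaEmbedding-class].
#' @export
pcaEmbed <- function(expr, r = 2) {
  X <- if (is(expr, "M7GExperiment")) exprValues(expr) else as.matrix(expr)
  sds <- rowSds(X)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from PCA")
    X <- X[sds > 0, , drop = FALSE]
  }
  if (r > min(dim(X))) stop("r exceeds min(genes, samples)")
  Z <- t(rowZscore(X)) # samples x genes, each gene centered/scaled
  sv <- svd(Z, nu = r, nv = r)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(r)], r)
  for (j in seq_len(r)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(X), paste0("PC", seq_len(r)))
  dimnames(scores) <- list(colnames(X), paste0("PC", seq_len(r)))
  ve <- sv$d^2 / sum(sv$d^2)
  new("PcaEmbedding", loadings = loadings, scores = scores,
      varExplained = ve[seq_len(r)])
}
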