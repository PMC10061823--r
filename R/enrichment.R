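# Single-sample gene-set scoring and over-representation analysis.

# Raw ssGSEA enrichment score for one sample: genes ordered by decreasing
# expression; ES = sum over positions of the weighted in-set ECDF minus the
# unweighted out-of-set ECDF. `r` = tie-averaged ascending ranks.
.ssgseaSample <- function(r, inSet, alpha) {
  ord <- order(r, decreasing = TRUE)
  inOrd <- inSet[ord]
  w <- abs(r[ord])^alpha * inOrd
  pin <- cumsum(w) / sum(w)
  pout <- cumsum(!inOrd) / sum(!inOrd)
  sum(pin - pout)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks on ties)
#' and each gene set's score is the summed difference between the
#' rank-weighted in-set ECDF (weight `|rank|^alpha`) and the unweighted
#' out-of-set ECDF, walked over all genes in decreasing expression order.
#' Optionally the whole score matrix is normalized by its (max - min).
#' Sets with no member in the matrix are flagged (NA row, recorded in the
#' result) rather than raising an error; a set equal to the whole gene
#' universe is an error.
#'
#' @param expr an [M7GExperiment-class] or genes x samples matrix.
#' @param sets a [GeneSetCollection-class].
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize divide all scores by the matrix-wide (max - min)?
#' @return An [EnrichmentMatrix-class] (sets x samples).
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  X <- if (is(expr, "M7GExperiment")) exprValues(expr) else as.matrix(expr)
  if (nrow(X) < 2) stop("need >= 2 genes")
  genes <- rownames(X)
  ranks <- apply(X, 2, rank) # ascending, average ties
  es <- matrix(NA_real_, length(sets), ncol(X),
               dimnames = list(names(sets), colnames(X)))
  failed <- character()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (!length(members)) {
      failed <- c(failed, nm)
      next
    }
    if (length(members) == length(genes))
      stop("set equals universe: ", nm)
    inSet <- genes %in% members
    es[nm, ] <- apply(ranks, 2, .ssgseaSample, inSet = inSet, alpha = alpha)
  }
  if (length(failed))
    warning("set(s) with no overlap left unscored: ",
            paste(failed, collapse = ", "))
  if (normalize) {
    rng <- range(es, na.rm = TRUE)
    if (diff(rng) > 0) es <- es / diff(rng)
  }
  new("EnrichmentMatrix", scores = es, alpha = alpha,
      normalized = normalize, failedSets = failed)
}

#' Immune and stromal signature scores
#'
#' Tumor-microenvironment summary scores: the raw (unnormalized) ssGSEA
#' enrichment score of an immune and a stromal signature, per sample.
#'
#' @param expr an [M7GExperiment-class] or genes x samples matrix.
#' @param immuneSet,stromalSet character vectors of signature genes.
#' @param alpha rank-weighting exponent.
#' @return data.frame with `sample_id`, `immune_score`, `stromal_score`.
#' @export
estimateScores <- function(expr, immuneSet, stromalSet, alpha = 0.25) {
  sets <- GeneSetCollection(list(immune = immuneSet, stromal = stromalSet))
  em <- ssgsea(expr, sets, alpha = alpha, normalize = FALSE)
  if (length(em@failedSets))
    stop("signature(s) do not overlap the matrix: ",
         paste(em@failedSets, collapse = ", "))
  s <- enrichmentScores(em)
  data.frame(sample_id = colnames(s), immune_score = s["immune", ],
             stromal_score = s["stromal", ], row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a selected gene
#' list within a finite universe, BH-adjusted across sets and sorted by
#' adjusted p.
#'
#' @param selected character vector of selected genes (subset of `universe`,
#'   non-empty).
#' @param sets a [GeneSetCollection-class]; each set is intersected with the
#'   universe.
#' @param universe character vector of all testable genes.
#' @return `OraTable` data.frame: set, overlap, set size, list size,
#'   universe size, hypergeometric p and BH-adjusted p.
#' @export
ora <- function(selected, sets, universe) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!length(selected)) stop("selected gene list is empty")
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    k <- length(intersect(set, selected))
    K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, list_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$p)
  out[order(out$padj, out$p), , drop = FALSE]
}
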