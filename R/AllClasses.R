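#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.EXPR_UNITS <- c("raw_tpm", "log2_tpm1")

#' Expression container for modification-pattern analysis
#'
#' `M7GExperiment` is a thin [SummarizedExperiment::SummarizedExperiment]
#' subclass holding one genes-by-samples assay (`"expr"`), a per-sample cohort
#' label in `colData`, and a unit tag (`"raw_tpm"` or `"log2_tpm1"`) in
#' `metadata(x)$unit`. Clinical columns attached by [alignSamples()] also live
#' in `colData`.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("M7GExperiment", contains = "SummarizedExperiment")

.validM7GExperiment <- function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  v <- SummarizedExperiment::assay(object, "expr")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  unit <- metadata(object)$unit
  if (is.null(unit) || !unit %in% .EXPR_UNITS)
    msg <- c(msg, sprintf("metadata unit must be one of %s",
                          paste(.EXPR_UNITS, collapse = ", ")))
  if (!"cohort" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'cohort' column")
  if (anyNA(v))
    msg <- c(msg, "expression values must not contain missing cells")
  if (identical(unit, "raw_tpm") && length(v) && min(v) < 0)
    msg <- c(msg, "raw_tpm values must be >= 0")
  if (length(msg)) msg else TRUE
}
setValidity("M7GExperiment", .validM7GExperiment)

#' Construct an M7GExperiment
#'
#' @param values numeric genes-by-samples matrix with row and column names.
#' @param unit `"raw_tpm"` or `"log2_tpm1"`.
#' @param cohort per-sample cohort labels (recycled if length 1).
#' @param colData optional extra per-sample columns (data.frame).
#' @return A validated [M7GExperiment-class] object.
#' @examples
#' m <- matrix(rexp(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' M7GExperiment(m, unit = "raw_tpm", cohort = "c1")
#' @export
M7GExperiment <- function(values, unit = c("raw_tpm", "log2_tpm1"),
                          cohort = "cohort1", colData = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- DataFrame(cohort = rep_len(as.character(cohort), ncol(values)),
                  row.names = colnames(values))
  if (!is.null(colData)) {
    colData <- as.data.frame(colData)
    for (nm in setdiff(colnames(colData), "cohort")) cd[[nm]] <- colData[[nm]]
  }
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd,
                             metadata = list(unit = unit))
  new("M7GExperiment", se)
}

#' @describeIn M7GExperiment the expression matrix (genes x samples).
#' @param x an `M7GExperiment`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

#' @describeIn M7GExperiment the unit tag.
#' @export
exprUnit <- function(x) metadata(x)$unit

#' @describeIn M7GExperiment named per-sample cohort labels.
#' @export
cohortLabels <- function(x) {
  stats::setNames(as.character(colData(x)$cohort), colnames(x))
}

#' @describeIn M7GExperiment per-sample clinical columns as a data.frame
#'   (everything in `colData` beyond `cohort`), or `NULL` when none exist.
#' @export
clinicalData <- function(x) {
  cd <- as.data.frame(colData(x))
  extra <- setdiff(colnames(cd), "cohort")
  if (!length(extra)) return(NULL)
  out <- cd[, extra, drop = FALSE]
  out$sample_id <- rownames(cd)
  out[, c("sample_id", extra), drop = FALSE]
}

setMethod("show", "M7GExperiment", function(object) {
  cat(sprintf("M7GExperiment: %d genes x %d samples [unit: %s]\n",
              nrow(object), ncol(object), exprUnit(object)))
  cat("cohorts:", paste(sprintf("%s(%d)", names(table(colData(object)$cohort)),
                                table(colData(object)$cohort)),
                        collapse = ", "), "\n")
  extra <- setdiff(colnames(colData(object)), "cohort")
  if (length(extra))
    cat("clinical columns:", paste(extra, collapse = ", "), "\n")
})

#' Named collection of gene sets
#'
#' Holds GMT-style gene sets: a named list of character vectors plus an
#' optional one-line description per set.
#'
#' @slot sets named list of character vectors (unique names, non-empty sets).
#' @slot description named character vector of per-set descriptions.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)) ||
        any(!nzchar(names(object@sets))))
      msg <- c(msg, "set names must be unique and non-empty")
    if (any(lengths(object@sets) == 0))
      msg <- c(msg, "every gene set must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors.
#' @param description optional named character of per-set descriptions.
#' @export
GeneSetCollection <- function(sets = list(), description = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description))
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  new("GeneSetCollection", sets = sets,
      description = description[names(sets)])
}

#' @describeIn GeneSetCollection the named list of member vectors.
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

setMethod("length", "GeneSetCollection", function(x) length(x@sets))
setMethod("names", "GeneSetCollection", function(x) names(x@sets))
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])
setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection of %d sets", length(object)))
  if (length(object))
    cat(sprintf(" (sizes %d-%d)", min(lengths(object@sets)),
                max(lengths(object@sets))))
  cat("\n")
  for (nm in utils::head(names(object), 5))
    cat(sprintf("  %s: %d genes\n", nm, length(object@sets[[nm]])))
  if (length(object) > 5) cat(sprintf("  ... and %d more\n", length(object) - 5))
})

#' Empirical-Bayes batch model estimates
#'
#' Per-(gene, batch) location/scale estimates from [batchAdjust()]: raw batch
#' effects, their shrunken (posterior) counterparts and the method-of-moments
#' prior hyperparameters.
#'
#' @slot gammaHat,gammaStar genes x batches matrices of additive effects
#'   (raw and shrunken) on the standardized scale.
#' @slot deltaHatSq,deltaStarSq genes x batches matrices of multiplicative
#'   (variance) effects, all positive.
#' @slot hyper per-batch list with prior parameters
#'   (`gamma.bar`, `t2`, `a.prior`, `b.prior`).
#' @slot batches character vector of batch labels.
#' @export
setClass("BatchModel",
         representation(gammaHat = "matrix", gammaStar = "matrix",
                        deltaHatSq = "matrix", deltaStarSq = "matrix",
                        hyper = "list", batches = "character"))

setValidity("BatchModel", function(object) {
  msg <- character()
  dims <- lapply(list(object@gammaHat, object@gammaStar,
                      object@deltaHatSq, object@deltaStarSq), dim)
  if (length(unique(dims)) != 1)
    msg <- c(msg, "all effect matrices must share dimensions")
  if (any(object@deltaStarSq <= 0) || any(object@deltaHatSq < 0))
    msg <- c(msg, "variance effects must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BatchModel", function(object) {
  cat(sprintf("BatchModel: %d genes x %d batches (%s)\n",
              nrow(object@gammaHat), length(object@batches),
              paste(object@batches, collapse = ", ")))
})

#' Consensus clustering result
#'
#' @slot consensus list (by k) of samples x samples consensus matrices.
#' @slot assignments samples x k integer matrix of cluster labels per k.
#' @slot cdf list (by k) of data.frames (`value`, `cdf`).
#' @slot areaUnderCdf,deltaArea,pac numeric vectors indexed by k.
#' @slot chosenK selected number of clusters.
#' @slot kRange,reps,pItem,seed configuration echo.
#' @export
setClass("ConsensusResult",
         representation(consensus = "list", assignments = "matrix",
                        cdf = "list", areaUnderCdf = "numeric",
                        deltaArea = "numeric", pac = "numeric",
                        chosenK = "integer", kRange = "integer",
                        reps = "integer", pItem = "numeric", seed = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (m in object@consensus) {
    if (!isSymmetric(unname(m), tol = 1e-12))
      msg <- c(msg, "consensus matrices must be symmetric")
    if (min(m) < 0 || max(m) > 1)
      msg <- c(msg, "consensus entries must lie in [0, 1]")
  }
  for (j in seq_along(object@kRange)) {
    k <- object@kRange[j]
    if (length(unique(object@assignments[, j])) != k)
      msg <- c(msg, sprintf("assignment for k = %d must have %d non-empty clusters", k, k))
  }
  if (!object@chosenK %in% object@kRange)
    msg <- c(msg, "chosenK must be inside kRange")
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn ConsensusResult cluster labels (integer vector named by sample)
#'   for `k` (default the chosen k).
#' @param x a `ConsensusResult`.
#' @param k number of clusters to extract.
#' @export
clusterAssignments <- function(x, k = x@chosenK) {
  j <- match(k, x@kRange)
  if (is.na(j)) stop("k = ", k, " was not evaluated")
  x@assignments[, j]
}

#' @describeIn ConsensusResult consensus matrix for `k`.
#' @export
consensusMatrix <- function(x, k = x@chosenK) {
  j <- match(k, x@kRange)
  if (is.na(j)) stop("k = ", k, " was not evaluated")
  x@consensus[[j]]
}

#' @describeIn ConsensusResult chosen number of clusters.
#' @export
chosenK <- function(x) x@chosenK

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult over k = %s (reps = %d, pItem = %.2f)\n",
              paste(range(object@kRange), collapse = "-"),
              object@reps, object@pItem))
  cat(sprintf("chosen k = %d; PAC: %s\n", object@chosenK,
              paste(sprintf("k%d=%.3f", object@kRange, object@pac),
                    collapse = " ")))
  cat("cluster sizes at chosen k:",
      paste(table(clusterAssignments(object)), collapse = "/"), "\n")
})

#' PCA embedding of an expression subset
#'
#' @slot loadings genes x r matrix, columns orthonormal.
#' @slot scores samples x r matrix of projections.
#' @slot varExplained fraction of variance per component, non-increasing.
#' @export
setClass("PcaEmbedding",
         representation(loadings = "matrix", scores = "matrix",
                        varExplained = "numeric"))

setValidity("PcaEmbedding", function(object) {
  msg <- character()
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "loadings must be column-orthonormal")
  ve <- object@varExplained
  if (any(diff(ve) > 1e-12) || sum(ve) > 1 + 1e-8)
    msg <- c(msg, "explained-variance fractions must be non-increasing and sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PcaEmbedding", function(object) {
  cat(sprintf("PcaEmbedding: %d genes, %d samples, %d components\n",
              nrow(object@loadings), nrow(object@scores),
              ncol(object@loadings)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varExplained), collapse = ", "), "\n")
})

#' Single-sample enrichment score matrix
#'
#' @slot scores sets x samples matrix of enrichment scores; rows for sets with
#'   no overlap with the expression universe are `NA` and listed in
#'   `failedSets`.
#' @slot alpha rank-weighting exponent used.
#' @slot normalized whether matrix-wide (max - min) normalization was applied.
#' @slot failedSets names of sets that could not be scored.
#' @export
setClass("EnrichmentMatrix",
         representation(scores = "matrix", alpha = "numeric",
                        normalized = "logical", failedSets = "character"))

setValidity("EnrichmentMatrix", function(object) {
  ok <- object@scores[!rownames(object@scores) %in% object@failedSets, ,
                      drop = FALSE]
  msg <- character()
  if (anyNA(ok) || (length(ok) && any(!is.finite(ok))))
    msg <- c(msg, "scored entries must be finite")
  if (isTRUE(object@normalized) && length(ok) &&
      (min(ok) < -1 - 1e-9 || max(ok) > 1 + 1e-9))
    msg <- c(msg, "normalized scores must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EnrichmentMatrix the sets x samples score matrix.
#' @param x an `EnrichmentMatrix`.
#' @export
enrichmentScores <- function(x) x@scores

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix: %d sets x %d samples (alpha = %.2f%s)\n",
              nrow(object@scores), ncol(object@scores), object@alpha,
              if (object@normalized) ", normalized" else ""))
  if (length(object@failedSets))
    cat("unscored sets:", paste(object@failedSets, collapse = ", "), "\n")
})

#' Maximally selected log-rank cutpoint
#'
#' @slot cutoff the selected threshold (a candidate score value).
#' @slot statistics data.frame of candidates and standardized log-rank
#'   statistics (`cutpoint`, `z`).
#' @slot minprop minimum group proportion enforced on both sides.
#' @slot groupSizes named integer vector (`low`, `high`) at the optimum.
#' @export
setClass("CutpointResult",
         representation(cutoff = "numeric", statistics = "data.frame",
                        minprop = "numeric", groupSizes = "integer"))

setValidity("CutpointResult", function(object) {
  msg <- character()
  if (!object@cutoff %in% object@statistics$cutpoint)
    msg <- c(msg, "cutoff must be one of the evaluated candidates")
  n <- sum(object@groupSizes)
  if (any(object@groupSizes < ceiling(object@minprop * n)))
    msg <- c(msg, "both groups must satisfy the minimum proportion")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CutpointResult", function(object) {
  cat(sprintf("CutpointResult: cutoff = %.6g (minprop = %.2f, groups %d/%d)\n",
              object@cutoff, object@minprop,
              object@groupSizes["low"], object@groupSizes["high"]))
})

#' Per-sample m7G score result
#'
#' @slot score named per-sample score (projection on PC1 plus PC2).
#' @slot genes gene list the score was built on.
#' @slot loadings genes x 2 loading matrix after sign orientation.
#' @slot orientation length-2 vector of signs applied to the components.
#' @slot hrDirection named hazard ratios used for orientation.
#' @slot cutoff maximally selected cutoff (`NA` before [stratify()]).
#' @slot group named character, `"high"`/`"low"` (empty before [stratify()]).
#' @slot logrank list with the two-group log-rank test of the stratification.
#' @export
setClass("ScoreResult",
         representation(score = "numeric", genes = "character",
                        loadings = "matrix", orientation = "numeric",
                        hrDirection = "numeric", cutoff = "numeric",
                        group = "character", logrank = "list"))

setValidity("ScoreResult", function(object) {
  msg <- character()
  if (any(!is.finite(object@score)))
    msg <- c(msg, "scores must be finite for every sample")
  if (length(object@genes) &&
      !identical(rownames(object@loadings), object@genes))
    msg <- c(msg, "loadings rows must correspond 1-to-1 to the gene list")
  if (length(object@group)) {
    if (!all(object@group %in% c("high", "low")) ||
        length(object@group) != length(object@score))
      msg <- c(msg, "groups must label every sample high or low")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ScoreResult named numeric per-sample scores.
#' @param x a `ScoreResult`.
#' @export
sampleScores <- function(x) x@score

#' @describeIn ScoreResult named high/low group labels (empty until
#'   [stratify()] has been applied).
#' @export
scoreGroups <- function(x) x@group

#' @describeIn ScoreResult the survival cutoff (`NA` until [stratify()]).
#' @export
scoreCutoff <- function(x) x@cutoff

setMethod("show", "ScoreResult", function(object) {
  cat(sprintf("ScoreResult: %d samples, %d genes\n",
              length(object@score), length(object@genes)))
  cat(sprintf("score range [%.3f, %.3f]", min(object@score), max(object@score)))
  if (!is.na(object@cutoff))
    cat(sprintf("; cutoff %.6g (high %d / low %d)", object@cutoff,
                sum(object@group == "high"), sum(object@group == "low")))
  cat("\n")
})
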