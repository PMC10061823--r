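#' Log-normalize a raw TPM matrix
#'
#' Applies `log2(x + 1)` to a `raw_tpm` matrix and retags it as
#' `log2_tpm1`. Inputs are taken to be TPM already; the transform order is
#' TPM-then-log.
#'
#' @param expr an [M7GExperiment-class] with unit `"raw_tpm"`.
#' @return An [M7GExperiment-class] with unit `"log2_tpm1"`.
#' @export
logNormalize <- function(expr) {
  if (!identical(exprUnit(expr), "raw_tpm"))
    stop("logNormalize expects unit 'raw_tpm'")
  v <- exprValues(expr)
  if (min(v) < 0) stop("negative expression value in raw_tpm input")
  M7GExperiment(log2(v + 1), unit = "log2_tpm1",
                cohort = cohortLabels(expr),
                colData = clinicalData(expr))
}

#' Merge cohorts on their common gene set
#'
#' Concatenates samples across log-scale cohorts, restricting to the
#' intersection of gene ids and preserving each sample's cohort label.
#'
#' @param cohorts list of [M7GExperiment-class] objects, all `log2_tpm1`.
#' @return A single merged [M7GExperiment-class].
#' @export
mergeCohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  units <- vapply(cohorts, exprUnit, "")
  if (!all(units == "log2_tpm1"))
    stop("all cohorts must be log2_tpm1 before merging")
  if (length(cohorts) == 1) return(cohorts[[1]])
  genes <- Reduce(intersect, lapply(cohorts, rownames))
  if (!length(genes)) stop("empty gene intersection across cohorts")
  allIds <- unlist(lapply(cohorts, colnames))
  if (anyDuplicated(allIds))
    stop("duplicate sample ids across cohorts")
  vals <- do.call(cbind, lapply(cohorts, function(x) exprValues(x)[genes, ,
                                                                  drop = FALSE]))
  cohort <- unlist(lapply(cohorts, cohortLabels), use.names = FALSE)
  M7GExperiment(vals, unit = "log2_tpm1", cohort = cohort)
}

# Newton inversion used by the EB solvers; also used by moderatedT().
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Coupled EB posterior solution for one batch (location gamma, scale delta2).
.ebSolve <- function(Z, gammaHat, delta2Hat, gammaBar, t2, aPrior, bPrior) {
  n <- ncol(Z)
  gOld <- gammaHat
  dOld <- delta2Hat
  for (i in 1:200) {
    gNew <- (t2 * n * gammaHat + dOld * gammaBar) / (t2 * n + dOld)
    ss <- rowSums((Z - gNew)^2)
    dNew <- (0.5 * ss + bPrior) / (n / 2 + aPrior - 1)
    if (max(abs(gNew - gOld)) < 1e-6 && max(abs(dNew - dOld)) < 1e-6) {
      gOld <- gNew; dOld <- dNew; break
    }
    gOld <- gNew
    dOld <- dNew
  }
  list(gammaStar = gOld, deltaStar = dOld)
}

#' Empirical-Bayes batch adjustment
#'
#' Removes per-cohort location/scale batch effects from a merged log-scale
#' matrix by the parametric empirical-Bayes procedure: genes are standardized
#' against the pooled (intercept-only) model, per-(gene, batch) additive and
#' multiplicative effects are estimated, shrunk toward method-of-moments
#' normal / inverse-gamma priors, and removed. Each gene's overall mean and
#' variance are restored afterwards, so the grand mean is preserved exactly.
#' Zero-variance genes pass through unadjusted with a warning.
#'
#' @param expr a merged [M7GExperiment-class] (`log2_tpm1`) with >= 2
#'   cohorts of >= 2 samples each.
#' @return List with `expr` (adjusted matrix, same dimensions and ordering)
#'   and `model` (a [BatchModel-class]).
#' @export
batchAdjust <- function(expr) {
  if (!identical(exprUnit(expr), "log2_tpm1"))
    stop("batchAdjust expects unit 'log2_tpm1'")
  X <- exprValues(expr)
  batch <- factor(cohortLabels(expr))
  if (nlevels(batch) < 2)
    stop("batch adjustment requires >= 2 batches")
  nb <- table(batch)
  if (any(nb < 2))
    stop("every batch must contain >= 2 samples (batch ",
         paste(names(nb)[nb < 2], collapse = ", "), " does not)")
  n <- ncol(X)
  sds <- rowSds(X)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " zero-variance gene(s) passed through unadjusted")
  keep <- which(!flat)
  Xk <- X[keep, , drop = FALSE]

  batchMeans <- vapply(levels(batch), function(b) {
    rowMeans(Xk[, batch == b, drop = FALSE])
  }, numeric(nrow(Xk)))
  grand <- as.vector(batchMeans %*% (as.vector(nb) / n))
  resid <- Xk - batchMeans[, as.integer(batch)]
  varPooled <- rowSums(resid^2) / n
  varPooled[varPooled == 0] <- min(varPooled[varPooled > 0], 1e-8)
  Z <- (Xk - grand) / sqrt(varPooled)

  G <- nrow(Xk)
  B <- nlevels(batch)
  gammaHat <- gammaStar <- deltaHat <- deltaStar <-
    matrix(NA_real_, G, B, dimnames = list(rownames(Xk), levels(batch)))
  hyper <- vector("list", B)
  names(hyper) <- levels(batch)
  Zadj <- Z
  for (b in levels(batch)) {
    idx <- which(batch == b)
    Zb <- Z[, idx, drop = FALSE]
    gh <- rowMeans(Zb)
    dh <- rowSums((Zb - gh)^2) / (length(idx) - 1)
    gammaBar <- mean(gh)
    t2 <- stats::var(gh)
    m <- mean(dh)
    s2 <- stats::var(dh)
    aPrior <- (2 * s2 + m^2) / s2
    bPrior <- (m * s2 + m^3) / s2
    sol <- .ebSolve(Zb, gh, dh, gammaBar, t2, aPrior, bPrior)
    gammaHat[, b] <- gh
    deltaHat[, b] <- dh
    gammaStar[, b] <- sol$gammaStar
    deltaStar[, b] <- sol$deltaStar
    hyper[[b]] <- list(gamma.bar = gammaBar, t2 = t2,
                       a.prior = aPrior, b.prior = bPrior)
    Zadj[, idx] <- (Zb - sol$gammaStar) / sqrt(sol$deltaStar)
  }
  Xadj <- Zadj * sqrt(varPooled) + grand
  # restore each gene's overall mean and variance exactly
  mAdj <- rowMeans(Xadj)
  sAdj <- rowSds(Xadj)
  sAdj[sAdj == 0] <- 1
  Xadj <- (Xadj - mAdj) / sAdj * sds[keep] + rowMeans(Xk)

  out <- X
  out[keep, ] <- Xadj
  model <- new("BatchModel", gammaHat = gammaHat, gammaStar = gammaStar,
               deltaHatSq = deltaHat, deltaStarSq = deltaStar,
               hyper = hyper, batches = levels(batch))
  adj <- M7GExperiment(out, unit = "log2_tpm1",
                       cohort = cohortLabels(expr),
                       colData = clinicalData(expr))
  list(expr = adj, model = model)
}
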