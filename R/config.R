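#' Default m7G regulator gene list
#'
#' The 23-gene regulator set covering writers (METTL1/WDR4 and related
#' methyltransferase components), cap-binding readers (EIF4E family, NCBP1/2),
#' and decapping/metabolic erasers (DCP2, DCPS, NUDT family) commonly used to
#' define m7G modification patterns in glioma cohorts.
#'
#' @return Character vector of 23 gene symbols.
#' @export
m7gRegulators <- function() {
  c("METTL1", "WDR4", "NSUN2", "DCP2", "DCPS", "NUDT10", "NUDT11",
    "NUDT16", "NUDT3", "NUDT4", "AGO2", "CYFIP1", "EIF4E", "EIF4E2",
    "EIF4E3", "GEMIN5", "LARP1", "NCBP1", "NCBP2", "EIF4G3", "IFIT5",
    "SNUPN", "EIF3D")
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: the regulator list, screening
#' thresholds, consensus-clustering parameters, ssGSEA weight, survival
#' options, and the synthetic-cohort generator settings.
#'
#' @param regulators character vector of regulator gene symbols.
#' @param degP raw p-value threshold for the differential-expression screen.
#' @param coxP Wald p threshold of the univariate prognostic screen.
#' @param oraFdr BH-adjusted p threshold for over-representation calls.
#' @param kRange integer candidate cluster numbers, subset of 2..9.
#' @param reps number of resampling replicates for consensus clustering.
#' @param pItem per-replicate sample subsampling proportion in (0, 1].
#' @param ssgseaAlpha rank-weighting exponent of the ssGSEA statistic.
#' @param truncateYears follow-up horizon (years) for KM/log-rank display.
#' @param minprop minimum group proportion for the survival cutpoint.
#' @param cohortSizes named integer vector of per-cohort sample counts.
#' @param nPhenotype,nImmune,nStromal,nBackground synthetic gene counts.
#' @param delta planted regulator shift between patterns (log2 units, >= 0).
#' @param beta survival log-hazard coefficient on the latent risk.
#' @param immuneShift,stromalShift,hallmarkLoad planted expression effects of
#'   the immune/stromal signatures and hallmark gene risk loading.
#' @param batchShift,batchScale per-cohort additive offsets and noise scale
#'   factors applied on the log2 scale.
#' @param censorMax administrative censoring horizon in days.
#' @param baseHazard baseline exponential hazard per day.
#' @param mutMeanLow,mutMeanHigh Poisson mutation-count means for the two
#'   planted patterns.
#' @param responseIntercept,responseSlope logit intercept `a` and slope `b`
#'   of the therapy-response model `P(CR/PR) = plogis(a - b * L)`.
#' @param patternProb probability a sample belongs to pattern A.
#' @param exomeMb exome footprint (Mb) used as the TMB denominator.
#' @param seed default integer seed for pipeline stages.
#' @return A named list of class `"m7gConfig"`.
#' @examples
#' cfg <- m7gConfig(cohortSizes = c(c1 = 30, c2 = 30), nBackground = 50)
#' @export
m7gConfig <- function(regulators = m7gRegulators(),
                      degP = 0.05, coxP = 0.05, oraFdr = 0.05,
                      kRange = 2:9, reps = 1000, pItem = 0.8,
                      ssgseaAlpha = 0.25,
                      truncateYears = 10, minprop = 0.1,
                      cohortSizes = c(TCGA = 490, CGGA693 = 330, CGGA325 = 160),
                      nPhenotype = 80, nImmune = 30, nStromal = 30,
                      nBackground = 400,
                      delta = 1.5, beta = 0.9,
                      immuneShift = 1.0, stromalShift = 0.5,
                      hallmarkLoad = 0.4,
                      batchShift = NULL, batchScale = NULL,
                      censorMax = 3650, baseHazard = log(2) / 1095,
                      mutMeanLow = 5, mutMeanHigh = 20,
                      responseIntercept = -0.3, responseSlope = 1.5,
                      patternProb = 0.62,
                      exomeMb = 38, seed = 1L) {
  if (is.null(batchShift))
    batchShift <- stats::setNames(seq(0, by = 1, length.out = length(cohortSizes)) -
                                    (length(cohortSizes) - 1) / 2,
                                  names(cohortSizes))
  if (is.null(batchScale))
    batchScale <- stats::setNames(rep(1, length(cohortSizes)), names(cohortSizes))
  cfg <- list(regulators = as.character(regulators),
              degP = degP, coxP = coxP, oraFdr = oraFdr,
              kRange = as.integer(kRange), reps = as.integer(reps),
              pItem = pItem, ssgseaAlpha = ssgseaAlpha,
              truncateYears = truncateYears, minprop = minprop,
              cohortSizes = cohortSizes,
              nPhenotype = as.integer(nPhenotype),
              nImmune = as.integer(nImmune),
              nStromal = as.integer(nStromal),
              nBackground = as.integer(nBackground),
              delta = delta, beta = beta,
              immuneShift = immuneShift, stromalShift = stromalShift,
              hallmarkLoad = hallmarkLoad,
              batchShift = batchShift, batchScale = batchScale,
              censorMax = censorMax, baseHazard = baseHazard,
              mutMeanLow = mutMeanLow, mutMeanHigh = mutMeanHigh,
              responseIntercept = responseIntercept,
              responseSlope = responseSlope,
              patternProb = patternProb,
              exomeMb = exomeMb, seed = as.integer(seed))
  class(cfg) <- "m7gConfig"
  validateConfig(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' @param config object returned by [m7gConfig()] or [readConfig()].
#' @return `config`, invisibly, after checking invariants.
#' @export
validateConfig <- function(config) {
  stopifnot(inherits(config, "m7gConfig"))
  if (!(config$pItem > 0 && config$pItem <= 1))
    stop("pItem must lie in (0, 1]")
  if (!all(config$kRange >= 2 & config$kRange <= 9))
    stop("kRange must be a subset of [2, 9]")
  for (th in c("degP", "coxP", "oraFdr"))
    if (!(config[[th]] > 0 && config[[th]] < 1))
      stop(th, " must lie in (0, 1)")
  if (config$delta < 0) stop("delta must be >= 0")
  if (any(config$cohortSizes < 2)) stop("every cohort size must be >= 2")
  if (config$reps < 1) stop("reps must be >= 1")
  invisible(config)
}

#' Read / write an analysis configuration as YAML
#'
#' Only keys present in the file override the [m7gConfig()] defaults.
#'
#' @param path YAML file path.
#' @return [readConfig()] returns an `m7gConfig`; [writeConfig()] returns
#'   `path` invisibly.
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(m7gConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  raw <- raw[intersect(names(raw), known)]
  for (nm in c("cohortSizes", "batchShift", "batchScale"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(m7gConfig, raw)
}

#' @rdname readConfig
#' @param config an `m7gConfig`.
#' @export
writeConfig <- function(config, path) {
  validateConfig(config)
  out <- unclass(config)
  out$cohortSizes <- as.list(out$cohortSizes)
  out$batchShift <- as.list(out$batchShift)
  out$batchScale <- as.list(out$batchScale)
  yaml::write_yaml(out, path)
  invisible(path)
}
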