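# Synthetic multi-cohort generator with planted modification-pattern
# structure. Gene-level parameters are drawn from a dedicated substream and
# each cohort from its own substream, so resizing one cohort never perturbs
# the others and everything is reproducible bit-for-bit from (config, seed).

.geneLayout <- function(config) {
  pad <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  hallSize <- max(1L, config$nBackground %/% 22L)
  list(regulators = config$regulators,
       phenotype = pad("PHG", config$nPhenotype),
       immune = pad("IMM", config$nImmune),
       stromal = pad("STR", config$nStromal),
       background = pad("BG", config$nBackground),
       hallSize = hallSize)
}

.geneParams <- function(config, seed) {
  lay <- .geneLayout(config)
  genes <- c(lay$regulators, lay$phenotype, lay$immune, lay$stromal,
             lay$background)
  withSeed(deriveSeed(seed, "gene-params"), {
    mu <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
    regSign <- stats::setNames(sample(c(-1, 1), length(lay$regulators),
                                      replace = TRUE), lay$regulators)
    phLoad <- stats::setNames(sample(c(-1, 1), config$nPhenotype,
                                     replace = TRUE) *
                                stats::runif(config$nPhenotype, 0.8, 1.2),
                              lay$phenotype)
    gainP <- stats::setNames(stats::runif(length(lay$regulators), 0.02, 0.25),
                             lay$regulators)
    lossP <- stats::setNames(stats::runif(length(lay$regulators), 0.02, 0.25),
                             lay$regulators)
    list(layout = lay, genes = genes, mu = mu, regSign = regSign,
         phLoad = phLoad, phBlock = rep_len(1:3, config$nPhenotype),
         gainP = gainP, lossP = lossP)
  })
}

.simulateCohort <- function(config, gp, cohortName, n, seed) {
  lay <- gp$layout
  withSeed(deriveSeed(seed, paste0("cohort-", cohortName)), {
    ids <- sprintf("%s_S%04d", cohortName, seq_len(n))
    pattern <- ifelse(stats::runif(n) < config$patternProb, "A", "B")
    pe <- ifelse(pattern == "B", 1, -1)
    # standardized pattern effect (theoretical moments of the +/-1 coding)
    p <- config$patternProb
    m <- (1 - p) - p
    s <- sqrt(1 - m^2)
    L <- (pe - m) / s + stats::rnorm(n, 0, 0.5)
    gc <- cut(L + stats::rnorm(n, 0, 0.3), breaks = c(-Inf, -0.5, 0.5, Inf),
              labels = c("A", "B", "C"))
    gc <- as.character(gc)

    X <- matrix(0, length(gp$genes), n, dimnames = list(gp$genes, ids))
    X[lay$regulators, ] <- gp$mu[lay$regulators] +
      outer(gp$regSign * config$delta, -pe) + # pattern A = mu + sign*delta
      matrix(stats::rnorm(length(lay$regulators) * n), ncol = n)
    blockShift <- config$delta *
      (matrix(gp$phBlock, config$nPhenotype, n) ==
         matrix(match(gc, c("A", "B", "C")), config$nPhenotype, n,
                byrow = TRUE))
    X[lay$phenotype, ] <- gp$mu[lay$phenotype] + outer(gp$phLoad, L) +
      blockShift + matrix(stats::rnorm(config$nPhenotype * n), ncol = n)
    X[lay$immune, ] <- gp$mu[lay$immune] +
      matrix(config$immuneShift * (pattern == "B"), config$nImmune, n,
             byrow = TRUE) +
      matrix(stats::rnorm(config$nImmune * n), ncol = n)
    X[lay$stromal, ] <- gp$mu[lay$stromal] +
      matrix(config$stromalShift * (pattern == "B"), config$nStromal, n,
             byrow = TRUE) +
      matrix(stats::rnorm(config$nStromal * n), ncol = n)
    hallGenes <- lay$background[seq_len(11 * lay$hallSize)]
    X[lay$background, ] <- gp$mu[lay$background] +
      matrix(stats::rnorm(config$nBackground * n), ncol = n)
    X[hallGenes, ] <- X[hallGenes, ] +
      matrix(config$hallmarkLoad * L, length(hallGenes), n, byrow = TRUE)

    # per-cohort batch effect: scale the deviations, then shift
    shift <- config$batchShift[[cohortName]]
    scl <- config$batchScale[[cohortName]]
    X <- gp$mu + scl * (X - gp$mu) + shift

    rate <- config$baseHazard * exp(config$beta * L)
    T <- stats::rexp(n, rate)
    C <- stats::runif(n, 0, config$censorMax)
    os_time <- ceiling(pmin(T, C))
    os_event <- as.integer(T <= C)
    grade <- ifelse(stats::runif(n) < stats::plogis(0.8 * L), "G3", "G2")
    age <- pmin(pmax(round(stats::rnorm(n, 45, 12)), 18), 85)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    responder <- stats::runif(n) <
      stats::plogis(config$responseIntercept - config$responseSlope * L)
    response <- ifelse(responder,
                       sample(c("CR", "PR"), n, replace = TRUE,
                              prob = c(0.3, 0.7)),
                       sample(c("SD", "PD"), n, replace = TRUE))

    counts <- stats::rpois(n, ifelse(pattern == "A", config$mutMeanLow,
                                     config$mutMeanHigh))
    counts <- pmin(counts, length(gp$genes))
    classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
                 "Splice_Site", "Silent", "Intron")
    classP <- c(0.55, 0.10, 0.10, 0.05, 0.15, 0.05)
    mut <- do.call(rbind, lapply(which(counts > 0), function(i) {
      data.frame(sample_id = ids[i],
                 gene = sample(gp$genes, counts[i]),
                 variant_classification = sample(classes, counts[i],
                                                 replace = TRUE, prob = classP),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(mut))
      mut <- data.frame(sample_id = character(), gene = character(),
                        variant_classification = character())
    mut <- unique(mut)
    lut <- variantClassLookup()
    mut$is_nonsynonymous <- unname(lut[mut$variant_classification])

    cnvStates <- vapply(lay$regulators, function(g) {
      sample(c("gain", "loss", "neutral"), n, replace = TRUE,
             prob = c(gp$gainP[[g]], gp$lossP[[g]],
                      1 - gp$gainP[[g]] - gp$lossP[[g]]))
    }, character(n))
    cnv <- data.frame(sample_id = rep(ids, times = length(lay$regulators)),
                      gene = rep(lay$regulators, each = n),
                      state = as.vector(cnvStates),
                      stringsAsFactors = FALSE)

    list(values = X, ids = ids,
         clinical = data.frame(sample_id = ids, os_time = os_time,
                               os_event = os_event, grade = grade, age = age,
                               sex = sex, cohort = cohortName,
                               response = response, stringsAsFactors = FALSE),
         truth = data.frame(sample_id = ids, cohort = cohortName,
                            pattern = pattern, gene_cluster = gc, L = L,
                            stringsAsFactors = FALSE),
         mutations = mut, cnv = cnv)
  })
}

#' Simulate a multi-cohort meta-cohort with planted pattern structure
#'
#' Generates expression (raw TPM scale), clinical, mutation, copy-number and
#' therapy-response data for the cohorts named in `config$cohortSizes`, with
#' ground truth attached. Planted structure: two regulator expression
#' patterns A/B separated by `delta` log2 units per gene (random per-gene
#' sign); a latent risk `L` (standardized pattern effect plus noise) loading
#' on phenotype genes, which additionally carry a three-block structure tied
#' to the true gene-cluster label; exponential survival with log-hazard
#' `beta * L` under uniform administrative censoring; immune/stromal
#' signature genes elevated in pattern B; hallmark signature genes mildly
#' loaded on `L`; per-cohort additive/multiplicative batch effects; Poisson
#' mutation counts by pattern; and Bernoulli therapy response with logit
#' `a - b * L`.
#'
#' @param config an [m7gConfig()].
#' @param seed integer master seed; per-cohort and gene-parameter substreams
#'   are derived from it.
#' @return List with `expr` ([M7GExperiment-class], unit `"raw_tpm"`),
#'   `clinical`, `mutations`, `cnv`, and `truth` (per-sample latent risk,
#'   pattern and gene-cluster labels plus the planted parameters as
#'   attributes).
#' @examples
#' sim <- simulateMetaCohort(m7gConfig(cohortSizes = c(a = 20, b = 20),
#'                                     nBackground = 60), seed = 1)
#' sim$expr
#' @export
simulateMetaCohort <- function(config = m7gConfig(), seed = config$seed) {
  validateConfig(config)
  if (config$delta < 0) stop("delta must be >= 0")
  if (any(config$cohortSizes < 2)) stop("every cohort size must be >= 2")
  gp <- .geneParams(config, seed)
  parts <- lapply(names(config$cohortSizes), function(cn) {
    .simulateCohort(config, gp, cn, config$cohortSizes[[cn]], seed)
  })
  values <- do.call(cbind, lapply(parts, `[[`, "values"))
  raw <- pmax(2^values - 1, 0)
  cohort <- rep(names(config$cohortSizes), times = config$cohortSizes)
  expr <- M7GExperiment(raw, unit = "raw_tpm", cohort = cohort)
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  attr(truth, "delta") <- config$delta
  attr(truth, "beta") <- config$beta
  attr(truth, "batchShift") <- config$batchShift
  attr(truth, "responseSlope") <- config$responseSlope
  list(expr = expr,
       clinical = do.call(rbind, lapply(parts, `[[`, "clinical")),
       mutations = do.call(rbind, lapply(parts, `[[`, "mutations")),
       cnv = do.call(rbind, lapply(parts, `[[`, "cnv")),
       truth = truth)
}

#' Gene-set signatures matched to the synthetic generator
#'
#' Ships the toy signature collection aligned to the generated gene ids:
#' eleven hallmark-style sets (slices of the background genes that carry the
#' planted risk loading), the immune signature (exactly the generator's
#' immune-elevated genes) and the stromal signature. Membership is fully
#' determined by `config` (gene counts), independent of the seed.
#'
#' @param config an [m7gConfig()].
#' @return A [GeneSetCollection-class] with >= 13 sets.
#' @export
bundledSignatures <- function(config = m7gConfig()) {
  lay <- .geneLayout(config)
  sets <- lapply(seq_len(11), function(j) {
    lay$background[((j - 1) * lay$hallSize + 1):(j * lay$hallSize)]
  })
  names(sets) <- sprintf("HALLMARK_SIG%02d", seq_len(11))
  sets$IMMUNE_SIGNATURE <- lay$immune
  sets$STROMAL_SIGNATURE <- lay$stromal
  GeneSetCollection(sets)
}
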