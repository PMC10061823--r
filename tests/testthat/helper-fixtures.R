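# Shared small fixtures, built in code.

random_expr <- function(nGenes = 50, nSamples = 20, seed = 1,
                        unit = "log2_tpm1") {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples, 6, 2), nGenes, nSamples,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("S%03d", seq_len(nSamples))))
  if (unit == "raw_tpm") m <- abs(m)
  M7GExperiment(m, unit = unit)
}

small_config <- function(...) {
  m7gConfig(cohortSizes = c(a = 60, b = 50, c = 40), nBackground = 110,
            nPhenotype = 60, nImmune = 20, nStromal = 20,
            kRange = 2:4, reps = 50, ...)
}

# One small simulated meta-cohort shared across test files (computed once).
.sim_cache <- new.env()
shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$cfg <- small_config(delta = 2)
    .sim_cache$sim <- simulateMetaCohort(.sim_cache$cfg, seed = 101)
  }
  list(cfg = .sim_cache$cfg, sim = .sim_cache$sim)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
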