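# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# session stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from a parent seed and a label, kept
# below 2^31 so it is a valid R integer seed.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             (seq_along(utf8ToInt(as.character(label))) + 16L))
  as.integer((as.numeric(seed) * 48271 + h * 31 + 7) %% 2147483647)
}

rowSds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Row-wise z-score; zero-variance rows are flagged by the caller.
rowZscore <- function(x) {
  m <- rowMeans(x)
  s <- rowSds(x)
  (x - m) / s
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
}
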