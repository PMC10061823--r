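# Somatic mutation, copy-number and tumor-mutational-burden summaries.
# "Mutated" throughout means >= 1 nonsynonymous record; synonymous records
# are excluded from both frequencies and TMB.

#' Per-gene and overall mutation frequency
#'
#' Fraction of cohort samples with at least one nonsynonymous record, per
#' gene and overall (mutated in any listed gene), as percentages. Samples
#' absent from the mutation table count as unmutated.
#'
#' @param mut mutation data.frame ([readMutations()] layout).
#' @param cohortSamples character vector of all cohort sample ids.
#' @param genes genes to summarize (non-empty).
#' @return List with `perGene` (data.frame `gene`, `n_mutated`,
#'   `frequency_pct`) and `overall` (list `n_mutated`, `n`,
#'   `frequency_pct`).
#' @examples
#' mut <- data.frame(sample_id = paste0("s", 1:5), gene = "EIF4G3",
#'                   variant_classification = "Missense_Mutation",
#'                   is_nonsynonymous = TRUE)
#' mutationFrequency(mut, paste0("s", 1:505), "EIF4G3")$overall$frequency_pct
#' @export
mutationFrequency <- function(mut, cohortSamples, genes) {
  if (!length(genes)) stop("empty gene list")
  if (!length(cohortSamples)) stop("empty cohort")
  ns <- mut[mut$is_nonsynonymous & mut$gene %in% genes &
              mut$sample_id %in% cohortSamples, , drop = FALSE]
  n <- length(cohortSamples)
  perGene <- data.frame(gene = genes,
                        n_mutated = vapply(genes, function(g) {
                          length(unique(ns$sample_id[ns$gene == g]))
                        }, integer(1)),
                        row.names = NULL)
  perGene$frequency_pct <- 100 * perGene$n_mutated / n
  nOverall <- length(unique(ns$sample_id))
  list(perGene = perGene,
       overall = list(n_mutated = nOverall, n = n,
                      frequency_pct = 100 * nOverall / n))
}

#' Per-gene CNV gain/loss frequency
#'
#' @param cnv CNV data.frame ([readCnv()] layout).
#' @inheritParams mutationFrequency
#' @return data.frame with `gene`, `gain_pct`, `loss_pct` over the cohort.
#' @export
cnvFrequency <- function(cnv, cohortSamples, genes) {
  if (!length(genes)) stop("empty gene list")
  if (!length(cohortSamples)) stop("empty cohort")
  bad <- setdiff(unique(cnv$state), .CNV_STATES)
  if (length(bad))
    stop("CNV state(s) outside vocabulary: ", paste(bad, collapse = ", "))
  cnv <- cnv[cnv$sample_id %in% cohortSamples & cnv$gene %in% genes, ,
             drop = FALSE]
  n <- length(cohortSamples)
  data.frame(gene = genes,
             gain_pct = vapply(genes, function(g) {
               100 * sum(cnv$gene == g & cnv$state == "gain") / n
             }, numeric(1)),
             loss_pct = vapply(genes, function(g) {
               100 * sum(cnv$gene == g & cnv$state == "loss") / n
             }, numeric(1)),
             row.names = NULL)
}

#' Pairwise co-mutation association
#'
#' For each gene pair, builds the 2x2 mutated/unmutated sample table and
#' reports the two-sided Fisher exact p, odds ratio and phi coefficient,
#' with BH adjustment across pairs. Genes never observed mutated are
#' skipped (listed in `attr(x, "skipped")`).
#'
#' @inheritParams mutationFrequency
#' @return data.frame with one row per tested pair.
#' @export
coMutation <- function(mut, genes, cohortSamples = NULL) {
  genes <- unique(genes)
  if (length(genes) < 2) stop("need >= 2 genes")
  if (is.null(cohortSamples)) cohortSamples <- unique(mut$sample_id)
  ns <- mut[mut$is_nonsynonymous & mut$gene %in% genes, , drop = FALSE]
  ind <- vapply(genes, function(g) {
    cohortSamples %in% ns$sample_id[ns$gene == g]
  }, logical(length(cohortSamples)))
  observed <- genes[colSums(ind) > 0]
  skipped <- setdiff(genes, observed)
  if (length(skipped))
    message("skipping never-mutated gene(s): ",
            paste(skipped, collapse = ", "))
  if (length(observed) < 2) {
    out <- data.frame(gene1 = character(), gene2 = character(),
                      both = integer(), only1 = integer(), only2 = integer(),
                      neither = integer(), odds_ratio = numeric(),
                      phi = numeric(), p = numeric(), padj = numeric())
    attr(out, "skipped") <- skipped
    return(out)
  }
  pairs <- utils::combn(observed, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- ind[, g1]; y <- ind[, g2]
    tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)), 2)
    ft <- stats::fisher.test(tab)
    phi <- suppressWarnings(stats::cor(x, y))
    data.frame(gene1 = g1, gene2 = g2, both = tab[1, 1], only1 = tab[2, 1],
               only2 = tab[1, 2], neither = tab[2, 2],
               odds_ratio = unname(ft$estimate), phi = phi,
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$p)
  attr(out, "skipped") <- skipped
  out
}

#' Tumor mutational burden per sample
#'
#' Nonsynonymous record count per sample divided by the exome footprint in
#' megabases. Samples absent from the mutation table score 0; TMB is
#' additive over concatenated tables.
#'
#' @inheritParams mutationFrequency
#' @param exomeMb exome size in Mb (> 0), default 38.
#' @return Named numeric vector of TMB (mutations/Mb) per cohort sample.
#' @export
tmb <- function(mut, cohortSamples, exomeMb = 38) {
  if (!(exomeMb > 0)) stop("exomeMb must be > 0")
  ns <- mut[mut$is_nonsynonymous & mut$sample_id %in% cohortSamples, ,
            drop = FALSE]
  counts <- table(factor(ns$sample_id, levels = cohortSamples))
  stats::setNames(as.numeric(counts) / exomeMb, cohortSamples)
}
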