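#' Run the full modification-pattern pipeline
#'
#' Orchestrates the analysis end to end in the standard order: simulate (or
#' accept) a multi-cohort dataset, log-normalize and batch-adjust, consensus
#' clustering of regulator expression into the two m7G patterns, moderated-t
#' differential expression between patterns, univariate prognostic screen of
#' the DEGs, consensus clustering of the screened phenotype genes into three
#' gene clusters, the PCA-based m7G score with survival stratification,
#' hallmark/TME enrichment by score group, mutation/CNV/TMB summaries, and
#' the score-response association. All randomness derives from `seed`;
#' survival-dependent stages are skipped (status `"skipped: no outcome"`)
#' when the clinical table lacks survival columns.
#'
#' @param config an [m7gConfig()]; consensus k values default to 2 (patterns)
#'   and 3 (gene clusters), mirroring the cluster counts this analysis design
#'   fixes by CDF inspection.
#' @param seed integer master seed.
#' @param data optional precomputed input list with elements `expr`
#'   (raw-TPM [M7GExperiment-class]), `clinical` (or `NULL`), `mutations`,
#'   `cnv`; when `NULL` the synthetic generator supplies them.
#' @param outDir optional directory; when given, headline tables are written
#'   as TSV and the run report as `report.json`.
#' @param patternK,geneClusterK consensus cluster counts for the two
#'   clustering stages.
#' @return A `RunReport` list: per-stage `status` and wall-clock seconds,
#'   headline `tables`, the fitted objects in `objects`, and a config/seed
#'   echo.
#' @export
runAll <- function(config = m7gConfig(), seed = config$seed, data = NULL,
                   outDir = NULL, patternK = 2, geneClusterK = 3) {
  validateConfig(config)
  report <- list(stages = list(), tables = list(), seed = as.integer(seed),
                 config = list(regulators = config$regulators,
                               degP = config$degP, coxP = config$coxP,
                               reps = config$reps, pItem = config$pItem,
                               minprop = config$minprop,
                               truncateYears = config$truncateYears))
  objects <- list()
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      report$stages[[name]] <<- list(status = paste("error:",
                                                    conditionMessage(e)),
                                     seconds = proc.time()[["elapsed"]] - t0)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = round(proc.time()[["elapsed"]] - t0,
                                                   3))
    res
  }
  skipStage <- function(name, why) {
    report$stages[[name]] <<- list(status = paste0("skipped: ", why),
                                   seconds = 0)
    NULL
  }

  if (is.null(data)) {
    data <- runStage("simulate", function() {
      simulateMetaCohort(config, seed = deriveSeed(seed, "simulate"))
    })
  } else {
    report$stages[["simulate"]] <- list(status = "skipped: data supplied",
                                        seconds = 0)
  }
  hasSurvival <- !is.null(data$clinical) &&
    all(c("os_time", "os_event") %in% colnames(data$clinical))

  prep <- runStage("preprocess", function() {
    lg <- logNormalize(data$expr)
    if (length(unique(cohortLabels(lg))) >= 2 &&
        all(table(cohortLabels(lg)) >= 2)) batchAdjust(lg)$expr else lg
  })

  if (hasSurvival) {
    aligned <- runStage("align", function() alignSamples(prep, data$clinical))
    prep <- aligned$expr
    clin <- aligned$clinical
  } else {
    skipStage("align", "no outcome")
    clin <- NULL
  }

  regPresent <- intersect(config$regulators, rownames(prep))
  patterns <- runStage("cluster_patterns", function() {
    cc <- consensusCluster(prep[regPresent, ], kRange = config$kRange,
                           reps = config$reps, pItem = config$pItem,
                           seed = deriveSeed(seed, "patterns"),
                           kOverride = patternK)
    cc
  })
  patLabels <- stats::setNames(paste0("P", clusterAssignments(patterns)),
                               colnames(prep))
  report$tables$pattern_sizes <- as.list(table(patLabels))
  objects$patterns <- patterns

  deg <- runStage("deg", function() {
    candidates <- setdiff(rownames(prep), regPresent)
    tab <- moderatedT(prep[candidates, ], patLabels)
    tab[order(tab$p), ]
  })
  degGenes <- deg$gene[deg$p < config$degP]
  report$tables$n_deg <- length(degGenes)
  objects$deg <- deg

  if (hasSurvival) {
    screen <- runStage("prognostic_screen", function() {
      prognosticScreen(prep, clin, degGenes, alpha = config$coxP)
    })
    keptGenes <- attr(screen, "kept")
    objects$screen <- screen
  } else {
    skipStage("prognostic_screen", "no outcome")
    keptGenes <- degGenes
    screen <- NULL
  }
  report$tables$n_prognostic <- length(keptGenes)

  geneClusters <- if (length(keptGenes) >= 2) {
    runStage("gene_clusters", function() {
      consensusCluster(prep[keptGenes, ], kRange = config$kRange,
                       reps = config$reps, pItem = config$pItem,
                       seed = deriveSeed(seed, "gene-clusters"),
                       kOverride = geneClusterK)
    })
  } else skipStage("gene_clusters", "fewer than 2 phenotype genes")
  if (!is.null(geneClusters)) {
    gcLabels <- stats::setNames(paste0("G", clusterAssignments(geneClusters)),
                                colnames(prep))
    report$tables$gene_cluster_sizes <- as.list(table(gcLabels))
    objects$geneClusters <- geneClusters
  } else gcLabels <- NULL

  if (hasSurvival && length(keptGenes) >= 2) {
    scoreRes <- runStage("score", function() {
      hr <- stats::setNames(screen$HR, screen$gene)
      sr <- m7gScore(prep[keptGenes, ], hr)
      stratify(sr, clin$os_time, clin$os_event, minprop = config$minprop,
               truncateYears = config$truncateYears)
    })
    objects$score <- scoreRes
    report$tables$score_cutoff <- scoreCutoff(scoreRes)
    report$tables$score_logrank_p <- scoreRes@logrank$p
    report$tables$score_group_sizes <- as.list(table(scoreGroups(scoreRes)))
    if (!is.null(gcLabels)) {
      xt <- scoreGroupCrosstab(patLabels, gcLabels, sampleScores(scoreRes))
      report$tables$cluster_crosstab_kruskal_p <- xt$kruskal$p
    }
  } else {
    skipStage("score", "no outcome")
    scoreRes <- NULL
  }

  enrich <- runStage("enrichment", function() {
    sigs <- bundledSignatures(config)
    present <- vapply(names(sigs), function(nm) {
      any(sigs[[nm]] %in% rownames(prep))
    }, TRUE)
    sigs <- GeneSetCollection(geneSets(sigs)[present])
    hall <- ssgsea(prep, sigs, alpha = config$ssgseaAlpha)
    tme <- estimateScores(prep, sigs[["IMMUNE_SIGNATURE"]],
                          sigs[["STROMAL_SIGNATURE"]],
                          alpha = config$ssgseaAlpha)
    list(hallmark = hall, tme = tme)
  })
  objects$enrichment <- enrich
  immune <- stats::setNames(enrich$tme$immune_score, enrich$tme$sample_id)
  report$tables$immune_by_pattern_p <-
    rankTests(immune, patLabels[names(immune)], "wilcoxon2")$p

  alt <- runStage("alterations", function() {
    samples <- colnames(prep)
    mf <- mutationFrequency(data$mutations, samples, config$regulators)
    cf <- cnvFrequency(data$cnv, samples, config$regulators)
    burden <- tmb(data$mutations, samples, exomeMb = config$exomeMb)
    list(mutationFrequency = mf, cnvFrequency = cf, tmb = burden)
  })
  objects$alterations <- alt
  report$tables$overall_mutation_pct <- alt$mutationFrequency$overall$frequency_pct
  if (!is.null(scoreRes)) {
    grp <- scoreGroups(scoreRes)
    report$tables$tmb_by_group_p <-
      rankTests(alt$tmb[names(grp)], grp, "wilcoxon2")$p
  }

  if (!is.null(scoreRes) && !is.null(clin) && "response" %in% colnames(clin)) {
    resp <- runStage("response", function() {
      responseAssociation(sampleScores(scoreRes), scoreGroups(scoreRes),
                          clin$response)
    })
    report$tables$response_wilcoxon_p <- resp$wilcoxon$p
    objects$response <- resp
  } else {
    skipStage("response", if (is.null(scoreRes)) "no outcome"
              else "no response labels")
  }

  report$objects <- objects
  if (!is.null(outDir)) writeRunReport(report, outDir)
  report
}

#' Persist a run report
#'
#' Writes headline tables as TSV and a JSON report (stage statuses, seed,
#' thresholds, headline numbers) under `outDir`.
#'
#' @param report list returned by [runAll()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  obj <- report$objects
  if (!is.null(obj$score)) {
    sc <- data.frame(sample_id = names(sampleScores(obj$score)),
                     m7g_score = unname(sampleScores(obj$score)),
                     group = unname(scoreGroups(obj$score)))
    utils::write.table(sc, file.path(outDir, "m7g_score.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(obj$deg))
    utils::write.table(obj$deg, file.path(outDir, "deg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(obj$patterns)) {
    pa <- data.frame(sample_id = rownames(obj$patterns@assignments),
                     obj$patterns@assignments)
    utils::write.table(pa, file.path(outDir, "pattern_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(seed = report$seed, config = report$config,
               stages = report$stages, tables = report$tables,
               r_version = as.character(getRversion()))
  jsonlite::write_json(meta, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
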