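#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with one header row of sample ids, gene ids in
#' the first column, and numeric cells. Gene ids are whitespace-trimmed and
#' matched case-sensitively. Duplicate gene rows are collapsed to the row with
#' the highest mean expression (with a warning); duplicate sample ids are an
#' error; non-numeric or missing cells are an error naming the offending
#' row/column.
#'
#' @param path TSV file.
#' @param unit `"raw_tpm"` or `"log2_tpm1"`.
#' @param cohort per-sample cohort labels, recycled if length 1.
#' @return An [M7GExperiment-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, unit = c("raw_tpm", "log2_tpm1"),
                           cohort = "cohort1") {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples")
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- trimws(df[[1]])
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]) | is.na(df[[j + 1]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   bad[1] + 1L, samples[j]))
    vals[, j] <- v
  }
  rownames(vals) <- genes
  if (anyDuplicated(genes)) {
    dupes <- unique(genes[duplicated(genes)])
    warning("collapsing duplicate gene row(s) to highest-mean row: ",
            paste(dupes, collapse = ", "))
    keep <- vapply(split(seq_along(genes), genes), function(idx) {
      idx[which.max(rowMeans(vals[idx, , drop = FALSE]))]
    }, integer(1))
    keep <- sort(unname(keep))
    vals <- vals[keep, , drop = FALSE]
  }
  M7GExperiment(vals, unit = unit, cohort = cohort)
}

#' Write an expression matrix to TSV
#'
#' @param x an [M7GExperiment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), exprValues(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table
#'
#' A TSV with one row per sample. `sample_id`, `os_time` (days) and
#' `os_event` (0/1) are required for survival analysis; further columns
#' (`grade`, `age`, `sex`, `cohort`, `response`, mutation-status columns)
#' pass through unchanged. `sample_id` must be unique.
#'
#' @param path TSV file.
#' @return [readClinical()] returns a data.frame.
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot_cols(df, "sample_id", "clinical table")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  df
}

#' @rdname readClinical
#' @param clin clinical data.frame.
#' @export
writeClinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Lines with fewer than three fields raise an error naming the line number;
#' an empty file yields an empty collection with a warning.
#'
#' @param path GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(GeneSetCollection())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop(sprintf("GMT format error at line %d: fewer than 3 fields", short[1]))
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate set name(s) in GMT")
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), nm)
  desc <- stats::setNames(vapply(parts, `[[`, "", 2), nm)
  GeneSetCollection(sets, desc)
}

#' Write gene sets in GMT format
#'
#' @param sets a [GeneSetCollection-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets@description[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Variant classes regarded as nonsynonymous (MAF-style vocabulary).
.NONSYN_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                     "Nonstop_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
                     "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
                     "Translation_Start_Site")
.SYN_CLASSES <- c("Silent", "Synonymous", "Intron", "RNA", "IGR",
                  "3'UTR", "5'UTR", "3'Flank", "5'Flank")

#' Variant-classification vocabulary
#'
#' The declared lookup mapping MAF-style variant classes to nonsynonymous
#' status. Classes outside the vocabulary are treated as synonymous (i.e.
#' excluded from mutation frequency and TMB) with a warning on read.
#'
#' @return Named logical vector: `TRUE` = nonsynonymous.
#' @export
variantClassLookup <- function() {
  stats::setNames(c(rep(TRUE, length(.NONSYN_CLASSES)),
                    rep(FALSE, length(.SYN_CLASSES))),
                  c(.NONSYN_CLASSES, .SYN_CLASSES))
}

#' Read / write a mutation table
#'
#' MAF-like TSV with columns `sample_id`, `gene`, `variant_classification`.
#' An `is_nonsynonymous` column is derived from [variantClassLookup()] (and
#' re-derived on read if present). Fully duplicated records are dropped with
#' a warning.
#'
#' @param path TSV file.
#' @return [readMutations()] returns a data.frame with the four columns.
#' @export
readMutations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("sample_id", "gene", "variant_classification"),
                 "mutation table")
  df <- df[, c("sample_id", "gene", "variant_classification")]
  if (anyDuplicated(df)) {
    warning("dropping fully duplicated mutation record(s)")
    df <- unique(df)
  }
  lut <- variantClassLookup()
  unknown <- setdiff(unique(df$variant_classification), names(lut))
  if (length(unknown))
    warning("variant class(es) outside vocabulary treated as synonymous: ",
            paste(unknown, collapse = ", "))
  df$is_nonsynonymous <- unname(lut[df$variant_classification])
  df$is_nonsynonymous[is.na(df$is_nonsynonymous)] <- FALSE
  rownames(df) <- NULL
  df
}

#' @rdname readMutations
#' @param mut mutation data.frame.
#' @export
writeMutations <- function(mut, path) {
  utils::write.table(mut[, c("sample_id", "gene", "variant_classification")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.CNV_STATES <- c("gain", "loss", "neutral")

#' Read / write a copy-number call table
#'
#' TSV with columns `sample_id`, `gene`, `state` in
#' `{gain, loss, neutral}`; one state per (sample, gene).
#'
#' @param path TSV file.
#' @return [readCnv()] returns a data.frame.
#' @export
readCnv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("sample_id", "gene", "state"), "CNV table")
  bad <- setdiff(unique(df$state), .CNV_STATES)
  if (length(bad))
    stop("CNV state(s) outside vocabulary: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[, c("sample_id", "gene")]))
    stop("multiple CNV states for one (sample, gene) pair")
  rownames(df) <- NULL
  df
}

#' @rdname readCnv
#' @param cnv CNV data.frame.
#' @export
writeCnv <- function(cnv, path) {
  utils::write.table(cnv[, c("sample_id", "gene", "state")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align expression and clinical samples
#'
#' Restricts both objects to the intersection of sample ids (in matched
#' order) and applies the clinical exclusion rules: overall survival time
#' shorter than one day, or missing survival time/status, drops a sample.
#' Every exclusion is counted by reason in the attached log. The operation
#' is idempotent.
#'
#' @param expr an [M7GExperiment-class].
#' @param clin clinical data.frame with `sample_id`, `os_time`, `os_event`.
#' @return List with `expr`, `clinical` (aligned), and `dropped` — a named
#'   integer count per exclusion reason.
#' @export
alignSamples <- function(expr, clin) {
  stopifnot_cols(clin, c("sample_id", "os_time", "os_event"), "clinical table")
  common <- intersect(colnames(expr), clin$sample_id)
  dropped <- c(not_in_both = (ncol(expr) - length(common)) +
                 (nrow(clin) - length(common)))
  if (!length(common)) stop("no samples shared between expression and clinical")
  clin <- clin[match(common, clin$sample_id), , drop = FALSE]
  bad_missing <- is.na(clin$os_time) | is.na(clin$os_event)
  bad_short <- !bad_missing & clin$os_time < 1
  dropped["missing_status"] <- sum(bad_missing)
  dropped["os_lt_1day"] <- sum(bad_short)
  keep <- common[!(bad_missing | bad_short)]
  if (!length(keep)) stop("no samples remain after clinical filtering")
  clin <- clin[match(keep, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  list(expr = expr[, keep], clinical = clin, dropped = dropped)
}
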