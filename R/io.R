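#' Read a probes-by-samples expression matrix from TSV
#'
#' The file must be tab-separated with a header row of sample identifiers
#' and probe identifiers in the first column. Values are log2 intensities
#' (or linear intensities if the downstream fold-change step is told so).
#' Duplicate probe or sample identifiers and non-finite cells are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with probe identifiers as row names and sample
#'   identifiers as column names.
#' @seealso [write_expression()], [read_design()], [standardize_rows()]
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file must have a probe-id column and >= 1 sample column")
  probes <- as.character(df[[1L]])
  dup <- probes[duplicated(probes)]
  if (length(dup) > 0L)
    stop("duplicate probe IDs in ", path, ": ",
         paste(utils::head(unique(dup), 5L), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  sdup <- colnames(m)[duplicated(colnames(m))]
  if (length(sdup) > 0L)
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(sdup), collapse = ", "))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing or non-finite value at probe '", rownames(m)[bad[1L, 1L]],
         "', sample '", colnames(m)[bad[1L, 2L]], "'")
  m
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that a written matrix
#' reads back bit-identically.
#'
#' @param em Numeric matrix with probe row names and sample column names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(em, path) {
  .check_matrix(em)
  header <- paste(c("probe_id", colnames(em)), collapse = "\t")
  body <- vapply(seq_len(nrow(em)), function(i) {
    paste(c(rownames(em)[i], sprintf("%.17g", em[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a time-course design table from TSV
#'
#' Columns: `sample_id`, `timepoint` (0-based ordinal; week labels in the
#' motivating design), `replicate` (1-based). Time points must form a
#' contiguous ordered set and every time point needs at least one replicate.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns `sample_id`, `timepoint`, `replicate`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "timepoint", "replicate")
  if (!all(need %in% names(df)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$timepoint <- as.integer(df$timepoint)
  df$replicate <- as.integer(df$replicate)
  .check_design(df)
  df
}

#' Write a design table as TSV
#' @param design Design `data.frame` (see [read_design()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path) {
  .check_design(design)
  utils::write.table(design[, c("sample_id", "timepoint", "replicate")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table from TSV
#'
#' Columns `probe_id` and `gene_symbol`; an empty symbol field marks an
#' unannotatable probe (stored as `NA`).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` with columns `probe_id`, `gene_symbol`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("probe_id", "gene_symbol")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$probe_id <- as.character(df$probe_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0L)
    stop("duplicate probe IDs in annotation: ",
         paste(utils::head(unique(dup), 5L), collapse = ", "))
  df
}

#' Write an annotation table as TSV
#' @param annotation `data.frame` with `probe_id`, `gene_symbol` (`NA` for
#'   unannotated probes, written as an empty field).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- annotation[, c("probe_id", "gene_symbol")]
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize each probe to mean 0, SD 1 across all samples
#'
#' The per-probe linear scaling applied to normalized expression values
#' before reporting: each row is affinely transformed to mean 0 and unit
#' standard deviation across the whole time course.
#'
#' @param em Numeric expression matrix (probes x samples).
#' @return A matrix of the same shape with every row at mean 0, SD 1.
#' @export
standardize_rows <- function(em) {
  .check_matrix(em)
  ctr <- em - rowMeans(em)
  s <- sqrt(rowSums(ctr^2) / (ncol(em) - 1L))
  zero <- which(s == 0 | !is.finite(s))
  if (length(zero) > 0L)
    stop("zero-variance rows cannot be standardized: ",
         paste(utils::head(rownames(em)[zero], 5L), collapse = ", "),
         if (length(zero) > 5L) sprintf(" (and %d more)", length(zero) - 5L))
  ctr / s
}

#' Per-probe mean expression at each time point
#'
#' Averages replicate arrays within each design time point, yielding the
#' probes x time-points matrix the PCA operates on.
#'
#' @param em Expression matrix (probes x samples).
#' @param design Design table covering exactly the matrix samples.
#' @return A numeric matrix, one column per time point (named `t0`, `t1`,
#'   ...), rows aligned with `em`.
#' @export
timepoint_means <- function(em, design) {
  .check_matrix(em)
  .check_design(design, em)
  tps <- sort(unique(design$timepoint))
  out <- vapply(tps, function(tp) {
    cols <- design$sample_id[design$timepoint == tp]
    rowMeans(em[, cols, drop = FALSE])
  }, numeric(nrow(em)))
  out <- matrix(out, nrow = nrow(em),
                dimnames = list(rownames(em), sprintf("t%d", tps)))
  out
}

# -- internal validators -----------------------------------------------------

.check_matrix <- function(em) {
  if (!is.matrix(em) || !is.numeric(em))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(em)) || is.null(colnames(em)))
    stop("expression matrix needs probe row names and sample column names")
  if (anyDuplicated(rownames(em)))
    stop("duplicate probe IDs: ",
         paste(utils::head(unique(rownames(em)[duplicated(rownames(em))]), 5L),
               collapse = ", "))
  if (anyDuplicated(colnames(em)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(em)[duplicated(colnames(em))]), collapse = ", "))
  bad <- which(!is.finite(em), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing or non-finite value at probe '", rownames(em)[bad[1L, 1L]],
         "', sample '", colnames(em)[bad[1L, 2L]], "'")
  invisible(em)
}

.check_design <- function(design, em = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "timepoint", "replicate") %in% names(design)))
    stop("design must be a data.frame with sample_id, timepoint, replicate")
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample IDs in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "))
  tps <- sort(unique(design$timepoint))
  if (any(is.na(tps)))
    stop("design time points must be integers")
  if (!identical(tps, seq(min(tps), max(tps))) && length(tps) > 1L)
    stop("design time points must form a contiguous ordered set, got: ",
         paste(tps, collapse = ", "))
  if (!is.null(em)) {
    extra <- setdiff(design$sample_id, colnames(em))
    if (length(extra) > 0L)
      stop("design sample(s) absent from the expression matrix: ",
           paste(extra, collapse = ", "))
    miss <- setdiff(colnames(em), design$sample_id)
    if (length(miss) > 0L)
      stop("matrix sample(s) absent from the design: ",
           paste(miss, collapse = ", "))
  }
  invisible(design)
}
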