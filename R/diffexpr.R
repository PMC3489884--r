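#' Fold change at each time point relative to a baseline
#'
#' Fold changes are computed from replicate means: on the log2 scale (the
#' default) `FC(g, t) = 2^(mean_t(g) - mean_baseline(g))`; for matrices of
#' linear intensities the ratio of means is taken instead.
#'
#' @param em Expression matrix (probes x samples).
#' @param design Design table.
#' @param baseline Baseline time point (default: the earliest).
#' @param scale `"log2"` (default) or `"linear"` — the scale of `em`.
#' @return A `tc_foldchange` list: `fc` (linear fold change, probes x time
#'   points; exactly 1 at the baseline column), `log2fc`, `baseline`,
#'   `timepoints`.
#' @export
fold_change <- function(em, design, baseline = NULL,
                        scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  mpm <- timepoint_means(em, design)
  tps <- sort(unique(design$timepoint))
  if (is.null(baseline)) baseline <- min(tps)
  if (!baseline %in% tps)
    stop("baseline time point ", baseline, " absent from the design")
  bcol <- match(baseline, tps)
  if (scale == "log2") {
    log2fc <- mpm - mpm[, bcol]
    fc <- 2^log2fc
  } else {
    if (any(mpm <= 0))
      stop("linear-scale fold change requires positive mean intensities")
    fc <- mpm / mpm[, bcol]
    log2fc <- log2(fc)
  }
  fc[, bcol] <- 1  # exact at the baseline
  log2fc[, bcol] <- 0
  structure(list(fc = fc, log2fc = log2fc, baseline = baseline,
                 timepoints = tps), class = "tc_foldchange")
}

#' Threshold a fold-change table into up- and down-regulated probe lists
#'
#' @param fct A `tc_foldchange` from [fold_change()].
#' @param cutoff Fold-change cut-off (> 1); the comparison is inclusive, so
#'   a probe at exactly the cut-off is selected. Default 3.29.
#' @param timepoint Time point to threshold at (default: the last).
#' @return A list with character vectors `up` (FC >= cutoff) and `down`
#'   (FC <= 1/cutoff); the lists are disjoint.
#' @export
threshold_fold_change <- function(fct, cutoff = 3.29, timepoint = NULL) {
  if (!inherits(fct, "tc_foldchange"))
    stop("fct must come from fold_change()")
  if (!is.numeric(cutoff) || cutoff <= 1) stop("cutoff must be > 1")
  if (is.null(timepoint)) timepoint <- max(fct$timepoints)
  tcol <- match(timepoint, fct$timepoints)
  if (is.na(tcol)) stop("time point ", timepoint, " absent from the table")
  fc <- fct$fc[, tcol]
  list(up = rownames(fct$fc)[fc >= cutoff],
       down = rownames(fct$fc)[fc <= 1 / cutoff])
}

#' Gene-level differential expression between two sample groups
#'
#' Per-gene two-sample t-test with pooled variance on log2 values,
#' Bonferroni-corrected across all genes — the gene-level comparison of an
#' undifferentiated population against a reference tissue profile.
#'
#' @param em_a,em_b Matrices sharing row (gene) identifiers; each must have
#'   at least 2 columns (replicates).
#' @param alpha Significance level applied to the adjusted p-value.
#' @return A data frame sorted by adjusted p then decreasing absolute
#'   difference: `gene`, `diff` (mean log2 difference, a minus b),
#'   `t`, `p`, `p_adj` (`min(1, p * n_tests)`), `significant`.
#' @export
compare_to_reference <- function(em_a, em_b, alpha = 0.05) {
  .check_matrix(em_a); .check_matrix(em_b)
  if (ncol(em_a) < 2L || ncol(em_b) < 2L)
    stop("each group needs at least 2 replicate columns")
  if (!setequal(rownames(em_a), rownames(em_b)))
    stop("the two matrices must share their gene identifiers")
  em_b <- em_b[rownames(em_a), , drop = FALSE]
  n1 <- ncol(em_a); n2 <- ncol(em_b)
  m1 <- rowMeans(em_a); m2 <- rowMeans(em_b)
  v1 <- rowSums((em_a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((em_b - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  d <- m1 - m2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  df <- n1 + n2 - 2L
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_adj <- pmin(1, p * length(p))
  out <- data.frame(gene = rownames(em_a), diff = d, t = tstat, p = p,
                    p_adj = p_adj, significant = p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_adj, out$p, -abs(out$diff)), , drop = FALSE]
}

#' Export a gene list for a protein-network service
#'
#' Writes one symbol per line, whitespace-trimmed, de-duplicated, in stable
#' first-occurrence order — the plain-text format accepted by interaction
#' network query pages.
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @return The path, invisibly. An empty (post-cleaning) list produces a
#'   warning and an empty file.
#' @export
export_network_list <- function(genes, path) {
  g <- trimws(as.character(genes))
  g <- g[!is.na(g) & g != ""]
  g <- g[!duplicated(g)]
  if (length(g) == 0L)
    warning("empty gene list: writing an empty file")
  writeLines(g, path)
  invisible(path)
}
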