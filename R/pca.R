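#' Principal component analysis of the time-point covariance matrix
#'
#' Eigendecomposition of the time-point x time-point covariance matrix of
#' the per-probe mean profiles (columns centered across probes, `n - 1`
#' denominator). Components are unit-length temporal profiles ordered by
#' decreasing eigenvalue. In the motivating replicated time course the first
#' component captures the general expression level, the second the monotone
#' change with time, and the third a transient mid-course elevation or dip.
#'
#' @param mpm Mean-profile matrix from [timepoint_means()] (probes x time
#'   points).
#' @return A `tc_components` object: `rotation` (time points x components),
#'   `eigenvalues`, `variance_fraction`, `timepoints`, and an `oriented`
#'   flag (initially `FALSE`).
#' @seealso [orient_components()], [factor_scores()]
#' @export
fit_pca <- function(mpm) {
  if (!is.matrix(mpm) || !is.numeric(mpm))
    stop("mpm must be a numeric matrix of per-time-point means")
  if (nrow(mpm) < 2L) stop("need at least 2 probes")
  if (ncol(mpm) < 2L) stop("need at least 2 time points")
  cc <- stats::cov(mpm)
  total <- sum(diag(cc))
  if (!is.finite(total) || total <= 0)
    stop("zero total variance: all probe profiles are identical")
  e <- eigen(cc, symmetric = TRUE)
  rot <- e$vectors
  dimnames(rot) <- list(colnames(mpm), sprintf("PC%d", seq_len(ncol(rot))))
  structure(list(rotation = rot,
                 eigenvalues = e$values,
                 variance_fraction = e$values / sum(e$values),
                 timepoints = colnames(mpm),
                 oriented = FALSE),
            class = "tc_components")
}

#' Resolve the sign ambiguity of the temporal components
#'
#' Eigenvectors are only defined up to sign. Orientation makes factor-score
#' signs interpretable: component 1 is flipped so its mean entry is
#' positive (a positive score means a high overall level); component 2 so
#' its dot product with the ascending time index is positive (a positive
#' score means expression increases with time); component 3 so its mean
#' over interior time points exceeds its mean over the two endpoints (a
#' positive score means a transient elevation). Further components are
#' flipped so their largest-magnitude entry is positive. Exact ties are
#' resolved towards +1 with a message. The map is deterministic and
#' idempotent.
#'
#' @param cs A `tc_components` object from [fit_pca()].
#' @return The same object with signs fixed and `oriented = TRUE`.
#' @export
orient_components <- function(cs) {
  if (!inherits(cs, "tc_components")) stop("cs must come from fit_pca()")
  v <- cs$rotation
  tt <- seq_len(nrow(v)) - 1L
  interior <- seq_len(nrow(v))[-c(1L, nrow(v))]
  crit <- function(j) {
    if (j == 1L) mean(v[, j])
    else if (j == 2L) sum(v[, j] * tt)
    else if (j == 3L) mean(v[interior, j]) - mean(v[c(1L, nrow(v)), j])
    else v[which.max(abs(v[, j])), j]
  }
  for (j in seq_len(ncol(v))) {
    cj <- crit(j)
    if (cj == 0) message("orientation tie for component ", j,
                         "; resolved towards +1")
    if (cj < 0) v[, j] <- -v[, j]
  }
  cs$rotation <- v
  cs$oriented <- TRUE
  cs
}

#' Per-probe factor scores by replicate regression on the components
#'
#' For every probe, ordinary least squares of its per-sample values on
#' components `1..k` evaluated at each sample's time point (replicates
#' share the regressor value). The components are the regression basis: no
#' separate intercept is added, because component 1 is (up to estimation
#' error) the constant general-level profile and an intercept would be
#' collinear with it, destroying the component 2 coefficient. The columns
#' are exactly orthogonal under a balanced replicated design, so the joint
#' and one-at-a-time coefficients coincide. Coefficient p-values are
#' two-sided t-tests of coefficient = 0 with `n_samples - k` residual
#' degrees of freedom — the replicate-based significance assessment. Each
#' coefficient column is then standardized across probes to mean 0, SD 1;
#' these standardized columns are the factor scores.
#'
#' @param em Expression matrix (probes x samples).
#' @param design Design table covering the matrix samples, with replication.
#' @param cs Component set (normally oriented; see [orient_components()]).
#' @param k Number of components regressed on (default 3).
#' @return A `tc_scores` object: `coefficients` (probes x k raw amplitudes),
#'   `scores` (standardized factor scores), `p.values`, residual `df`, `k`,
#'   and the `oriented` flag inherited from `cs`.
#' @export
factor_scores <- function(em, design, cs, k = 3L) {
  .check_matrix(em)
  .check_design(design, em)
  if (!inherits(cs, "tc_components")) stop("cs must come from fit_pca()")
  k <- as.integer(k)
  if (k < 1L || k > ncol(cs$rotation))
    stop("k must be between 1 and the number of components")
  n <- ncol(em)
  if (n <= k + 1L)
    stop("no residual degrees of freedom: need more than k + 1 = ",
         k + 1L, " samples, got ", n)
  tps <- sort(unique(design$timepoint))
  d <- design[match(colnames(em), design$sample_id), ]
  x <- cs$rotation[match(d$timepoint, tps), seq_len(k), drop = FALSE]
  xtxi <- solve(crossprod(x))
  bmat <- xtxi %*% crossprod(x, t(em))          # k x probes
  res <- t(em) - x %*% bmat
  df <- n - k
  s2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(xtxi), s2))
  tstat <- bmat / se
  pmat <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  b <- t(bmat)
  p <- t(pmat)
  colnames(b) <- sprintf("b%d", seq_len(k))
  colnames(p) <- sprintf("p%d", seq_len(k))
  csd <- apply(b, 2L, stats::sd)
  if (any(csd == 0 | !is.finite(csd)))
    stop("cannot standardize factor scores: a coefficient column has zero ",
         "spread across probes")
  f <- scale(b)
  dimnames(f) <- list(rownames(em), sprintf("f%d", seq_len(k)))
  structure(list(probe_id = rownames(em),
                 coefficients = b, scores = f, p.values = p,
                 sigma2 = s2, df = df, k = k,
                 oriented = isTRUE(cs$oriented)),
            class = "tc_scores")
}

#' Expected fraction of probes beyond a cut-off under a pure normal null
#'
#' If the factor scores followed a standard normal distribution (pure
#' noise), a two-sided cut-off of 3.29 SD would select 0.1% of probes and
#' each one-sided tail 0.05%.
#'
#' @param cutoff Non-negative cut-off in SD units.
#' @param sided `"two"` (default) or `"one"`.
#' @return The tail probability.
#' @examples
#' expected_null_fraction(3.29)          # ~0.001
#' expected_null_fraction(3.29, "one")   # ~0.0005
#' @export
expected_null_fraction <- function(cutoff, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stop("cutoff must be a non-negative number")
  tail <- stats::pnorm(cutoff, lower.tail = FALSE)
  if (sided == "two") 2 * tail else tail
}

#' Select outlying probes on their factor 2 and 3 scores
#'
#' A probe is selected when `max(|f2|, |f3|) >= cutoff` (inclusive) and,
#' when the significance filter is on, the triggering coefficient's
#' replicate-regression p-value is below `alpha`. Component 2 takes
#' precedence as the trigger when both exceed the cut-off; component 1
#' never triggers selection.
#'
#' @param fst A `tc_scores` object with `k >= 3`.
#' @param cutoff Selection cut-off in SD units (default 3.29).
#' @param alpha Significance level for the replicate filter (default 0.05).
#' @param require_significance Apply the filter? Default `TRUE`.
#' @return A `tc_selection` data frame: `probe_id`, `selected`, `component`
#'   (2, 3 or `NA`), `score`, `p`; attributes `cutoff`, `alpha`,
#'   `filtered`.
#' @export
select_probes <- function(fst, cutoff = 3.29, alpha = 0.05,
                          require_significance = TRUE) {
  if (!inherits(fst, "tc_scores")) stop("fst must come from factor_scores()")
  if (fst$k < 3L) stop("selection needs factor scores for components 2 and 3")
  if (!is.numeric(cutoff) || cutoff < 0) stop("cutoff must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  f2 <- fst$scores[, 2L]; f3 <- fst$scores[, 3L]
  p2 <- fst$p.values[, 2L]; p3 <- fst$p.values[, 3L]
  comp <- ifelse(abs(f2) >= cutoff, 2L, ifelse(abs(f3) >= cutoff, 3L, NA_integer_))
  score <- ifelse(comp == 2L, f2, f3)
  pval <- ifelse(comp == 2L, p2, p3)
  selected <- !is.na(comp) & (!require_significance | pval < alpha)
  out <- data.frame(probe_id = fst$probe_id,
                    selected = selected,
                    component = ifelse(selected, comp, NA_integer_),
                    score = ifelse(selected, score, NA_real_),
                    p = pval,
                    stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff, alpha = alpha,
            filtered = require_significance, class = c("tc_selection",
                                                       "data.frame"))
}

#' Classify selected probes into four temporal profile subgroups
#'
#' Among selected probes: `f2 <= -cutoff` gives subgroup 1 (peak at the
#' first time point, decreasing thereafter), `f2 >= +cutoff` subgroup 2
#' (increasing from the first time point onward); otherwise `f3 >= +cutoff`
#' gives subgroup 3 (short-term elevation) and `f3 <= -cutoff` subgroup 4
#' (short-term dip). Component 2 takes precedence, so the subgroups are
#' disjoint and exhaustive over the selection. Requires oriented
#' components, otherwise subgroup signs are undefined.
#'
#' @param fst The `tc_scores` object used for selection.
#' @param sel The `tc_selection` from [select_probes()].
#' @return `sel` with an integer `subgroup` column (`NA` for unselected).
#' @export
classify_subgroups <- function(fst, sel) {
  if (!inherits(fst, "tc_scores")) stop("fst must come from factor_scores()")
  if (!inherits(sel, "tc_selection")) stop("sel must come from select_probes()")
  if (!isTRUE(fst$oriented))
    stop("component set must be oriented before classification ",
         "(see orient_components)")
  cutoff <- attr(sel, "cutoff")
  f2 <- fst$scores[, 2L]; f3 <- fst$scores[, 3L]
  sub <- rep(NA_integer_, nrow(sel))
  i <- which(sel$selected)
  sub[i] <- ifelse(f2[i] <= -cutoff, 1L,
            ifelse(f2[i] >= cutoff, 2L,
            ifelse(f3[i] >= cutoff, 3L, 4L)))
  sel$subgroup <- sub
  sel
}

#' Attach gene symbols to a selection, discarding unannotatable probes
#'
#' Every selected probe must be present in the annotation table; probes
#' present but with an empty symbol are counted as unannotatable and
#' dropped from the gene table (mirroring the discard of probes that cannot
#' be matched to genes).
#'
#' @param sel Classified selection ([classify_subgroups()]).
#' @param annotation Annotation table (`probe_id`, `gene_symbol`).
#' @return A list: `genes` (data frame with `probe_id`, `gene_symbol`,
#'   `subgroup`, `component`, `score`, `p`) and `n_unannotated`.
#' @export
annotate_selection <- function(sel, annotation) {
  if (!inherits(sel, "tc_selection")) stop("sel must come from select_probes()")
  probes <- sel$probe_id[sel$selected]
  absent <- setdiff(probes, annotation$probe_id)
  if (length(absent) > 0L)
    stop("selected probe(s) absent from the annotation table: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  sym <- annotation$gene_symbol[match(probes, annotation$probe_id)]
  unann <- is.na(sym) | sym == ""
  keep <- sel[sel$selected, c("probe_id", "subgroup", "component",
                              "score", "p")]
  genes <- cbind(keep[!unann, , drop = FALSE],
                 gene_symbol = sym[!unann])[, c("probe_id", "gene_symbol",
                                                "subgroup", "component",
                                                "score", "p")]
  rownames(genes) <- NULL
  list(genes = genes, n_unannotated = sum(unann))
}
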