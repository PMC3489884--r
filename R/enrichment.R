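#' Hypergeometric upper-tail probability of a gene-set overlap
#'
#' `P(X >= overlap)` where `X` is the overlap of a uniform draw of
#' `list_size` genes from a universe of `universe_size` genes of which
#' `set_size` belong to the set — the exact over-representation p-value.
#' Vectorized over its arguments.
#'
#' @param overlap Observed overlap count(s).
#' @param list_size Size of the query gene list.
#' @param set_size Size of the gene set within the universe.
#' @param universe_size Size of the background universe.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_p(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_p <- function(overlap, list_size, set_size, universe_size) {
  n <- max(length(overlap), length(list_size), length(set_size),
           length(universe_size))
  overlap <- rep_len(overlap, n); list_size <- rep_len(list_size, n)
  set_size <- rep_len(set_size, n); universe_size <- rep_len(universe_size, n)
  if (any(overlap < 0) || any(overlap > pmin(list_size, set_size)))
    stop("overlap must lie in [0, min(list_size, set_size)]")
  if (any(set_size > universe_size) || any(list_size > universe_size))
    stop("set_size and list_size cannot exceed universe_size")
  stats::phyper(overlap - 1, set_size, universe_size - set_size, list_size,
                lower.tail = FALSE)
}

#' Gene-set over-representation test for a gene list
#'
#' Tests every set of a collection for over-representation in `gene_list`
#' against a background `universe` with the exact hypergeometric upper
#' tail (optionally the conservative EASE variant, which removes one
#' overlapping gene before taking the tail). List genes outside the
#' universe are reported and dropped; sets are intersected with the
#' universe.
#'
#' @param gene_list Character vector of query genes.
#' @param collection Named list of character vectors (e.g. [read_gmt()] or
#'   [generate_genesets()]).
#' @param universe Background gene population, e.g. all annotated genes on
#'   the array.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param alpha Significance level on the adjusted p-value.
#' @param ease Use the EASE variant? Default `FALSE` (plain exact test).
#' @return A `tc_enrichment` data frame sorted by adjusted p-value:
#'   `set`, `overlap`, `set_size`, `list_size`, `universe_size`, `p`,
#'   `p_adj`, `significant`; the universe-intersected memberships are kept
#'   in the `"sets"` attribute for [pathway_multiplicity()].
#' @export
enrich <- function(gene_list, collection, universe,
                   correction = c("bonferroni", "bh"), alpha = 0.05,
                   ease = FALSE) {
  correction <- match.arg(correction)
  universe <- unique(as.character(universe))
  universe <- universe[!is.na(universe) & universe != ""]
  if (length(universe) == 0L) stop("the universe is empty")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection must be a list of uniquely named gene sets")
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "))
    gene_list <- intersect(gene_list, universe)
  }
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  ov <- vapply(sets, function(s) length(intersect(s, gene_list)), integer(1L))
  ssz <- lengths(sets)
  lsz <- length(gene_list)
  usz <- length(universe)
  ov_test <- if (ease) pmax(ov - 1L, 0L) else ov
  p <- hypergeom_p(ov_test, lsz, ssz, usz)
  p_adj <- if (correction == "bonferroni") pmin(1, p * length(p))
           else stats::p.adjust(p, "BH")
  out <- data.frame(set = names(sets), overlap = ov, set_size = ssz,
                    list_size = lsz, universe_size = usz, p = p,
                    p_adj = p_adj, significant = p_adj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_adj, out$p, -out$overlap), , drop = FALSE]
  structure(out, sets = sets, gene_list = gene_list, alpha = alpha,
            class = c("tc_enrichment", "data.frame"))
}

#' Count, per gene, the significant sets it belongs to
#'
#' Some genes belong to a single over-represented pathway, others to two or
#' three; this tallies those multiplicities for the query genes. Genes in no
#' significant set are excluded from the histogram but reported.
#'
#' @param results A `tc_enrichment` from [enrich()].
#' @param gene_list Query genes (defaults to the list used in `enrich`).
#' @return A list: `multiplicity` (named counts for genes in >= 1
#'   significant set), `histogram` (`table` of genes by multiplicity), and
#'   `zero_set_genes`.
#' @export
pathway_multiplicity <- function(results, gene_list = attr(results,
                                                           "gene_list")) {
  if (!inherits(results, "tc_enrichment"))
    stop("results must come from enrich()")
  sets <- attr(results, "sets")
  sig <- results$set[results$significant]
  gene_list <- unique(as.character(gene_list))
  counts <- stats::setNames(integer(length(gene_list)), gene_list)
  for (s in sig) {
    hit <- gene_list %in% sets[[s]]
    counts[hit] <- counts[hit] + 1L
  }
  pos <- counts[counts > 0L]
  list(multiplicity = pos,
       histogram = if (length(pos)) table(pos) else table(integer(0)),
       zero_set_genes = names(counts)[counts == 0L])
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member gene symbols.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line(s) (need name, description, >= 1 gene): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  nm <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  structure(sets,
            description = stats::setNames(
              vapply(parts, `[[`, character(1L), 2L), nm))
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors; descriptions are taken from
#'   the `description` attribute (empty when absent).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
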