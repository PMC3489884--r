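#' Mean threshold cycle over replicate reactions
#'
#' @param replicates Numeric vector of Ct values (>= 1 finite value).
#' @return A list: `mean`, `sd` (`NA` for a single replicate), `n`.
#' @export
mean_ct <- function(replicates) {
  replicates <- as.numeric(replicates)
  replicates <- replicates[is.finite(replicates)]
  if (length(replicates) == 0L)
    stop("no finite Ct values in the replicate set")
  list(mean = mean(replicates),
       sd = if (length(replicates) > 1L) stats::sd(replicates) else NA_real_,
       n = length(replicates))
}

.plate_mean_ct <- function(plate, target, sample) {
  ct <- plate$Ct[plate$target == target & plate$sample == sample]
  if (length(ct) == 0L)
    stop("no Ct measurements for target '", target, "' in sample '",
         sample, "'")
  mean_ct(ct)$mean
}

#' Relative quantification by the 2^-ddCt method
#'
#' Mean Ct values per well are combined as
#' `dCt = Ct_target - Ct_reference` within each sample and
#' `ddCt = dCt_sample - dCt_calibrator`; the fold change of the target in
#' `sample` relative to `calibrator`, normalized to the housekeeping
#' `reference_gene`, is `2^-ddCt`. A base-10 log of the fold change is
#' returned alongside for plotting on a log scale.
#'
#' @param plate Long-format plate (`target`, `sample`, `replicate`, `Ct`),
#'   e.g. from [generate_qpcr()] or [read_qpcr()].
#' @param target Target gene.
#' @param sample Sample (condition / time point) to quantify.
#' @param reference_gene Housekeeping gene measured in every sample.
#' @param calibrator Calibrator sample (fold change 1 by construction).
#' @return A list: `fold_change`, `log10_fold_change`, `ddct`,
#'   `dct_sample`, `dct_calibrator`.
#' @export
ddct_fold_change <- function(plate, target, sample,
                             reference_gene = "REF",
                             calibrator = "calibrator") {
  need <- c("target", "sample", "Ct")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  dct_s <- .plate_mean_ct(plate, target, sample) -
    .plate_mean_ct(plate, reference_gene, sample)
  dct_c <- .plate_mean_ct(plate, target, calibrator) -
    .plate_mean_ct(plate, reference_gene, calibrator)
  ddct <- dct_s - dct_c
  fc <- 2^(-ddct)
  list(fold_change = fc, log10_fold_change = log10(fc), ddct = ddct,
       dct_sample = dct_s, dct_calibrator = dct_c)
}

#' 2^-ddCt fold changes for every target and sample on a plate
#'
#' @inheritParams ddct_fold_change
#' @return A data frame: `target`, `sample`, `ddct`, `fold_change`,
#'   `log10_fold_change` (one row per non-reference target per sample).
#' @export
ddct_table <- function(plate, reference_gene = "REF",
                       calibrator = "calibrator") {
  targets <- setdiff(unique(plate$target), reference_gene)
  samples <- unique(plate$sample)
  grid <- expand.grid(target = targets, sample = samples,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i)
    ddct_fold_change(plate, grid$target[i], grid$sample[i],
                     reference_gene, calibrator))
  grid$ddct <- vapply(res, `[[`, numeric(1L), "ddct")
  grid$fold_change <- vapply(res, `[[`, numeric(1L), "fold_change")
  grid$log10_fold_change <- vapply(res, `[[`, numeric(1L),
                                   "log10_fold_change")
  grid
}

#' Read a long-format qPCR plate from TSV
#'
#' Columns: `target`, `sample`, `replicate`, `Ct`. Ct values must be
#' positive and finite.
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` plate.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("target", "sample", "replicate", "Ct")
  if (!all(need %in% names(df)))
    stop("qPCR file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (any(!is.finite(df$Ct)) || any(df$Ct <= 0))
    stop("Ct values must be positive and finite")
  df
}

#' Write a qPCR plate as TSV
#' @param plate Long-format plate.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_qpcr <- function(plate, path) {
  utils::write.table(plate[, c("target", "sample", "replicate", "Ct")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
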