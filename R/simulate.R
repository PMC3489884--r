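#' Describe a block of probes sharing a planted temporal profile
#'
#' @param profile_class One of `"flat"`, `"sustained_increase"`,
#'   `"sustained_decrease"`, `"transient_peak"`, `"transient_dip"`.
#' @param n_probes Number of probes in the block.
#' @param effect_size Amplitude of the time trend in log2 units, measured as
#'   the centered L2 norm of the expected time-point profile (so it is the
#'   expected regression amplitude on the matching unit-length temporal
#'   component). For the 6-point transient tent this equals the
#'   peak-to-trough range; for the sustained linear ramp the peak-to-trough
#'   range is `effect_size / sqrt(0.35)` (about 1.69 x). Must be 0 for flat
#'   blocks.
#' @return A `planted_block` list.
#' @export
planted_block <- function(profile_class, n_probes, effect_size = 0) {
  classes <- c("flat", "sustained_increase", "sustained_decrease",
               "transient_peak", "transient_dip")
  profile_class <- match.arg(profile_class, classes)
  if (!is.numeric(n_probes) || length(n_probes) != 1L || n_probes < 1)
    stop("n_probes must be a positive count")
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be >= 0")
  if (profile_class == "flat" && effect_size != 0)
    stop("flat blocks must have effect_size = 0")
  structure(list(profile_class = profile_class,
                 n_probes = as.integer(n_probes),
                 effect_size = as.numeric(effect_size)),
            class = "planted_block")
}

#' Configuration of the synthetic time-course generator
#'
#' Defaults emulate a replicated six-time-point (weeks 0-5) microarray
#' design with duplicate arrays at each week: a dominant between-probe
#' baseline-level spread, additive Gaussian replicate noise on the log2
#' scale, and a quarter of probes left unannotatable.
#'
#' @param planted List of [planted_block()] objects; their sizes sum to the
#'   number of probes.
#' @param n_timepoints Number of time points (>= 3); default 6.
#' @param n_replicates Arrays per time point (>= 2, the significance filter
#'   requires replication); default 2.
#' @param baseline_mean,baseline_sd Per-probe baseline level distribution
#'   (log2 units); the baseline is drawn once per probe and shared across
#'   all of its samples.
#' @param noise_sd Replicate noise SD (log2 units).
#' @param frac_unannotated Fraction of probes without a gene symbol.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return A validated `sim_config` list with an `n_probes` field.
#' @export
sim_config <- function(planted,
                       n_timepoints = 6L,
                       n_replicates = 2L,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       noise_sd = 0.25,
                       frac_unannotated = 0.25,
                       seed = 1L) {
  if (inherits(planted, "planted_block")) planted <- list(planted)
  if (!is.list(planted) || length(planted) == 0L ||
      !all(vapply(planted, inherits, logical(1L), "planted_block")))
    stop("planted must be a non-empty list of planted_block objects")
  n_probes <- sum(vapply(planted, function(b) b$n_probes, integer(1L)))
  if (n_probes < 1L) stop("n_probes must be positive")
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3")
  if (n_replicates < 2L)
    stop("n_replicates must be >= 2: the replicate-based significance ",
         "filter requires replication at each time point")
  if (baseline_sd < 0 || noise_sd < 0) stop("standard deviations must be >= 0")
  if (frac_unannotated < 0 || frac_unannotated > 1)
    stop("frac_unannotated must be in [0, 1]")
  structure(list(planted = planted,
                 n_probes = as.integer(n_probes),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 noise_sd = noise_sd,
                 frac_unannotated = frac_unannotated,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Expected time-point profile for one probe class, anchored at 0 at t0 and
# scaled so the centered L2 norm equals `effect`. Sustained profiles are
# linear in the time index (strictly monotone); transient profiles are a
# symmetric tent over the interior time points (zero at both endpoints).
.profile_shape <- function(profile_class, n_timepoints, effect) {
  tt <- seq_len(n_timepoints) - 1L
  if (profile_class == "flat" || effect == 0) return(rep(0, n_timepoints))
  base <- switch(profile_class,
    sustained_increase = tt / (n_timepoints - 1L),
    sustained_decrease = -tt / (n_timepoints - 1L),
    transient_peak = { u <- pmin(tt, (n_timepoints - 1L) - tt); u / max(u) },
    transient_dip = { u <- pmin(tt, (n_timepoints - 1L) - tt); -u / max(u) })
  ctr <- base - mean(base)
  s <- effect * ctr / sqrt(sum(ctr^2))
  s - s[1L]
}

#' Generate a replicated time-course expression dataset with ground truth
#'
#' Each probe receives a baseline level drawn once from
#' `N(baseline_mean, baseline_sd^2)`, its block's expected temporal profile,
#' and independent `N(0, noise_sd^2)` replicate noise on the log2 scale.
#' Flat probes are baseline plus noise only; sustained profiles are strictly
#' monotone in expectation; transient profiles deviate only at interior time
#' points and have equal expected means at the first and last time points.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `expression` (probes x samples log2 matrix),
#'   `design` (sample_id, timepoint, replicate), `annotation` (probe_id,
#'   gene_symbol with `NA` for unannotatable probes), `truth` (probe_id,
#'   profile_class, effect_size, gene_symbol) and the `config`.
#' @examples
#' cfg <- sim_config(list(planted_block("flat", 200),
#'                        planted_block("sustained_increase", 20, 2)),
#'                   seed = 7)
#' sim <- simulate_timecourse(cfg)
#' dim(sim$expression)
#' @export
simulate_timecourse <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be created with sim_config()")
  set.seed(config$seed)
  n <- config$n_probes
  tp <- config$n_timepoints
  rep_n <- config$n_replicates

  cls <- unlist(lapply(config$planted,
                       function(b) rep(b$profile_class, b$n_probes)))
  eff <- unlist(lapply(config$planted,
                       function(b) rep(b$effect_size, b$n_probes)))
  probe_id <- sprintf("P%06d", seq_len(n))

  design <- data.frame(
    sample_id = sprintf("T%d_R%d", rep(seq_len(tp) - 1L, each = rep_n),
                        rep(seq_len(rep_n), times = tp)),
    timepoint = rep(seq_len(tp) - 1L, each = rep_n),
    replicate = rep(seq_len(rep_n), times = tp),
    stringsAsFactors = FALSE)

  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  shapes <- vapply(seq_along(config$planted), function(i) {
    b <- config$planted[[i]]
    .profile_shape(b$profile_class, tp, b$effect_size)
  }, numeric(tp))
  block_of <- rep(seq_along(config$planted),
                  vapply(config$planted, function(b) b$n_probes, integer(1L)))
  mu <- baseline + t(shapes)[block_of, , drop = FALSE]  # n x tp
  em <- mu[, design$timepoint + 1L, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd),
           nrow = n)
  dimnames(em) <- list(probe_id, design$sample_id)

  gene_symbol <- sprintf("GENE%06d", seq_len(n))
  n_un <- round(config$frac_unannotated * n)
  if (n_un > 0L) gene_symbol[sample.int(n, n_un)] <- NA_character_

  annotation <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                           stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probe_id, profile_class = cls,
                      effect_size = eff, gene_symbol = gene_symbol,
                      stringsAsFactors = FALSE)
  list(expression = em, design = design, annotation = annotation,
       truth = truth, config = config)
}

#' Generate a gene-set collection, optionally enriched for planted genes
#'
#' Draws gene sets from the annotated genes of a simulation truth table.
#' Designated "enriched" sets oversample genes carrying a non-flat planted
#' profile by `enrichment_factor` (sampling weight, without replacement);
#' the remaining "decoy" sets are uniform draws.
#'
#' @param truth Truth table from [simulate_timecourse()].
#' @param n_sets Number of sets (>= 1).
#' @param enrichment_factor Sampling weight multiplier (>= 1) for planted
#'   genes in enriched sets; 1 makes every set a uniform draw.
#' @param seed Integer seed.
#' @param set_size Genes per set (recycled across sets).
#' @param n_enriched Number of enriched sets; defaults to half of `n_sets`
#'   when `enrichment_factor > 1`, otherwise 0.
#' @return A named list of character vectors (names `ENRICHED_*`/`DECOY_*`)
#'   with attributes `description` and `enriched`; writable with
#'   [write_gmt()].
#' @export
generate_genesets <- function(truth, n_sets, enrichment_factor = 1,
                              seed = 1L, set_size = 100L,
                              n_enriched = if (enrichment_factor > 1)
                                ceiling(n_sets / 2) else 0L) {
  if (n_sets < 1L) stop("n_sets must be >= 1")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  ann <- !is.na(truth$gene_symbol) & truth$gene_symbol != ""
  if (!any(ann)) stop("truth table has no annotated genes")
  genes <- truth$gene_symbol[ann]
  planted <- truth$profile_class[ann] != "flat"
  sizes <- rep_len(as.integer(set_size), n_sets)
  if (any(sizes < 1L) || any(sizes > length(genes)))
    stop("set_size must be between 1 and the number of annotated genes")
  n_enriched <- min(as.integer(n_enriched), n_sets)
  set.seed(seed)
  w <- ifelse(planted, enrichment_factor, 1)
  sets <- vector("list", n_sets)
  nm <- character(n_sets)
  desc <- character(n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched) {
      sets[[i]] <- sample(genes, sizes[i], prob = w)
      nm[i] <- sprintf("ENRICHED_%02d", i)
      desc[i] <- sprintf("oversamples planted-profile genes (weight %g)",
                         enrichment_factor)
    } else {
      sets[[i]] <- sample(genes, sizes[i])
      nm[i] <- sprintf("DECOY_%02d", i - n_enriched)
      desc[i] <- "uniform random draw from the annotated genes"
    }
  }
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc,
            enriched = stats::setNames(seq_len(n_sets) <= n_enriched, nm))
}

#' Generate a synthetic qPCR plate with known fold changes
#'
#' Produces triplicate threshold-cycle (Ct) values for `n_targets` target
#' genes and one reference (housekeeping) gene `"REF"` in two conditions,
#' `"calibrator"` and `"treated"`, such that the expected 2^-ddCt fold
#' change of target `i` in `"treated"` vs `"calibrator"` equals
#' `fold_changes[i]`.
#'
#' @param n_targets Number of target genes.
#' @param fold_changes Positive fold changes, recycled to `n_targets`.
#' @param ct_ref Mean target Ct in the calibrator condition (cycles).
#' @param noise_sd Gaussian Ct noise SD (cycles); 0 gives exact recovery.
#' @param seed Integer seed.
#' @param n_replicates Replicate reactions per well (default triplicate).
#' @param ct_housekeeping Mean Ct of the reference gene (constant across
#'   conditions).
#' @return A `data.frame` with columns `target`, `sample`, `replicate`,
#'   `Ct`, plus attribute `fold_changes` (the planted values, named by
#'   target).
#' @export
generate_qpcr <- function(n_targets, fold_changes, ct_ref = 20,
                          noise_sd = 0, seed = 1L, n_replicates = 3L,
                          ct_housekeeping = 18) {
  if (n_targets < 1L) stop("n_targets must be >= 1")
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  fc <- rep_len(as.numeric(fold_changes), n_targets)
  targets <- sprintf("TG%02d", seq_len(n_targets))
  grid <- expand.grid(target = c(targets, "REF"),
                      sample = c("calibrator", "treated"),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$target == "REF", ct_housekeeping,
               ifelse(grid$sample == "calibrator", ct_ref,
                      ct_ref - log2(fc[match(grid$target, targets)])))
  grid$Ct <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  grid <- grid[order(grid$target, grid$sample, grid$replicate), ]
  rownames(grid) <- NULL
  attr(grid, "fold_changes") <- stats::setNames(fc, targets)
  grid
}

#' Write a simulated dataset to a directory of TSV files
#'
#' Writes `expression.tsv`, `design.tsv`, `annotation.tsv` and `truth.tsv`
#' in the dialects read by [read_expression()], [read_design()] and
#' [read_annotation()].
#'
#' @param sim Result of [simulate_timecourse()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  tr <- sim$truth
  tr$gene_symbol[is.na(tr$gene_symbol)] <- ""
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
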