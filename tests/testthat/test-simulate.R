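test_that("generator is deterministic and has the declared shape", {
  cfg <- sim_config(list(planted_block("flat", 100),
                         planted_block("sustained_increase", 10, 2)),
                    seed = 5)
  s1 <- simulate_timecourse(cfg)
  s2 <- simulate_timecourse(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_timecourse(sim_config(cfg$planted, seed = 6))
  expect_false(identical(s1$expression, s3$expression))

  expect_equal(dim(s1$expression), c(110L, 12L))
  expect_identical(rownames(s1$expression), s1$truth$probe_id)
  expect_identical(colnames(s1$expression), s1$design$sample_id)
  expect_setequal(s1$annotation$probe_id, s1$truth$probe_id)
  expect_false(anyDuplicated(s1$truth$probe_id) > 0)
})

test_that("planted profiles have the promised expected time courses", {
  cfg <- sim_config(list(planted_block("sustained_increase", 3, 1.5),
                         planted_block("sustained_decrease", 3, 1.5),
                         planted_block("transient_peak", 3, 1.5),
                         planted_block("transient_dip", 3, 1.5),
                         planted_block("flat", 3)),
                    noise_sd = 0, baseline_sd = 1, seed = 2)
  sim <- simulate_timecourse(cfg)
  mpm <- timepoint_means(sim$expression, sim$design)
  cls <- sim$truth$profile_class
  for (i in which(cls == "sustained_increase"))
    expect_true(all(diff(mpm[i, ]) > 0))
  for (i in which(cls == "sustained_decrease"))
    expect_true(all(diff(mpm[i, ]) < 0))
  for (i in which(cls %in% c("transient_peak", "transient_dip"))) {
    expect_equal(mpm[i, 1], mpm[i, 6])            # endpoints agree
    expect_false(all(mpm[i, 2:5] == mpm[i, 1]))   # deviates inside
  }
  for (i in which(cls == "transient_peak"))
    expect_true(all(mpm[i, 2:5] > mpm[i, 1]))
  for (i in which(cls == "transient_dip"))
    expect_true(all(mpm[i, 2:5] < mpm[i, 1]))
  for (i in which(cls == "flat"))
    expect_true(all(mpm[i, ] == mpm[i, 1]))
  # amplitude convention: centered L2 norm of the expected profile
  for (i in seq_len(nrow(mpm))[cls != "flat"]) {
    ctr <- mpm[i, ] - mean(mpm[i, ])
    expect_equal(sqrt(sum(ctr^2)), 1.5, tolerance = 1e-12)
  }
})

test_that("zero-noise flat data is rejected by the standardization step", {
  sim <- simulate_timecourse(sim_config(list(planted_block("flat", 5)),
                                        noise_sd = 0, seed = 1))
  expect_true(all(sim$expression == sim$expression[, 1]))
  expect_error(standardize_rows(sim$expression), "zero-variance")
})

test_that("configuration invariants are enforced", {
  blk <- list(planted_block("flat", 10))
  expect_error(sim_config(blk, n_replicates = 1), "replication")
  expect_error(sim_config(blk, n_timepoints = 2), "n_timepoints")
  expect_error(sim_config(blk, noise_sd = -1), ">= 0")
  expect_error(sim_config(blk, frac_unannotated = 1.2), "frac_unannotated")
  expect_error(sim_config(list()), "planted_block")
  expect_error(planted_block("flat", 10, effect_size = 1), "flat")
  expect_error(planted_block("wiggle", 10), "arg")
  expect_error(planted_block("sustained_increase", 0, 1), "positive")
})

test_that("unannotated fraction matches the configuration", {
  n <- 4000
  sim <- simulate_timecourse(sim_config(list(planted_block("flat", n)),
                                        frac_unannotated = 0.25, seed = 9))
  expect_equal(mean(is.na(sim$annotation$gene_symbol)), 0.25,
               tolerance = 1 / n)
  expect_identical(sim$truth$gene_symbol, sim$annotation$gene_symbol)
})

test_that("gene-set generator produces enriched and decoy sets", {
  sim <- simulate_timecourse(sim_config(
    list(planted_block("sustained_increase", 300, 1),
         planted_block("flat", 2700)), frac_unannotated = 0, seed = 3))
  gs <- generate_genesets(sim$truth, n_sets = 6, enrichment_factor = 10,
                          seed = 4, set_size = 100)
  expect_length(gs, 6L)
  expect_identical(sum(attr(gs, "enriched")), 3L)
  planted <- sim$truth$gene_symbol[sim$truth$profile_class != "flat"]
  frac <- vapply(gs, function(s) mean(s %in% planted), numeric(1))
  expect_gt(min(frac[attr(gs, "enriched")]), max(frac[!attr(gs, "enriched")]))

  # null factor: all sets are uniform draws
  gs0 <- generate_genesets(sim$truth, n_sets = 4, enrichment_factor = 1,
                           seed = 4, set_size = 100)
  expect_identical(sum(attr(gs0, "enriched")), 0L)

  bad <- sim$truth
  bad$gene_symbol <- NA_character_
  expect_error(generate_genesets(bad, 2), "no annotated genes")
  expect_error(generate_genesets(sim$truth, 0), "n_sets")
})

test_that("qPCR plate generator plants the requested fold changes", {
  plate <- generate_qpcr(2, c(1, 4), ct_ref = 22, noise_sd = 0, seed = 1)
  expect_setequal(unique(plate$target), c("TG01", "TG02", "REF"))
  expect_identical(nrow(plate), 18L)  # 3 genes x 2 samples x triplicate
  ct <- function(tg, s) unique(plate$Ct[plate$target == tg & plate$sample == s])
  expect_equal(ct("TG02", "calibrator") - ct("TG02", "treated"), log2(4))
  expect_error(generate_qpcr(1, 0), "> 0")
  expect_error(generate_qpcr(0, 1), "n_targets")
})
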