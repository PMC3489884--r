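test_that("a single shared profile puts all variance on component 1", {
  # probes differ only by an additive constant: rank-1 covariance
  profile <- c(1, 3, 2, 5, 4, 6)
  mpm <- outer(rnorm(20), rep(1, 6)) + rep(profile, each = 20)
  dimnames(mpm) <- list(sprintf("P%02d", 1:20), sprintf("t%d", 0:5))
  cs <- fit_pca(mpm)
  expect_equal(cs$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(abs(cs$rotation[, 1]), rep(1 / sqrt(6), 6), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("eigenvalues match characteristic-polynomial roots (oracle)", {
  for (seed in 1:5) {
    set.seed(seed)
    mpm <- matrix(rnorm(12), 4, 3,
                  dimnames = list(sprintf("P%d", 1:4), sprintf("t%d", 0:2)))
    cs <- fit_pca(mpm)
    expect_equal(cs$eigenvalues, charpoly_eigenvalues(cov(mpm)),
                 tolerance = 1e-8)
  }
})

test_that("component sets satisfy their algebraic invariants", {
  d <- make_design()
  m <- make_matrix(200, d, seed = 21, sd = 2)
  cs <- fit_pca(timepoint_means(m, d))
  g <- crossprod(cs$rotation)
  expect_true(max(abs(g - diag(ncol(g)))) < 1e-8)           # orthonormal
  expect_equal(sum(cs$eigenvalues), sum(diag(cov(timepoint_means(m, d)))),
               tolerance = 1e-9)                            # trace
  expect_equal(sum(cs$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(cs$eigenvalues) <= 1e-12))           # non-increasing
  expect_error(fit_pca(matrix(1, 5, 6,
                              dimnames = list(paste0("P", 1:5),
                                              paste0("t", 0:5)))),
               "zero total variance")
})

test_that("orientation fixes signs deterministically and idempotently", {
  tt <- 0:5
  ramp <- (tt - mean(tt)); ramp <- ramp / sqrt(sum(ramp^2))
  d <- make_design()
  cs <- fit_pca(timepoint_means(make_matrix(100, d, seed = 2), d))
  cs$rotation[, 2] <- -ramp                       # descending ramp
  o <- orient_components(cs)
  expect_equal(o$rotation[, 2], ramp, ignore_attr = TRUE)   # flipped back
  expect_identical(orient_components(o)$rotation, o$rotation) # idempotent
  expect_true(o$oriented)

  # property sweep: random orthonormal bases all satisfy the criteria
  for (seed in 1:100) {
    set.seed(seed)
    v <- qr.Q(qr(matrix(rnorm(36), 6)))
    cs$rotation <- v
    ov <- orient_components(cs)$rotation
    expect_gte(mean(ov[, 1]), 0)
    expect_gte(sum(ov[, 2] * tt), 0)
    expect_gte(mean(ov[2:5, 3]) - mean(ov[c(1, 6), 3]), 0)
  }
})

test_that("factor scores recover an exact component profile", {
  d <- make_design()
  m <- make_matrix(300, d, seed = 4)
  cs <- orient_components(fit_pca(timepoint_means(m, d)))
  amp <- c(0.5, 1, 2, -1)
  em <- t(vapply(amp, function(a)
    10 * cs$rotation[d$timepoint + 1, 1] + a * cs$rotation[d$timepoint + 1, 2],
    numeric(nrow(d))))
  dimnames(em) <- list(sprintf("P%d", 1:4), d$sample_id)
  fst <- factor_scores(em, d, cs)
  expect_equal(unname(fst$coefficients[, 2]), amp, tolerance = 1e-10)
  expect_equal(unname(fst$coefficients[, 3]), rep(0, 4), tolerance = 1e-10)
  expect_true(all(fst$sigma2 < 1e-20))            # exact fit
})

test_that("factor scores match a per-probe lm() fit (oracle)", {
  d <- make_design()
  em <- make_matrix(20, d, seed = 31)
  cs <- orient_components(fit_pca(timepoint_means(em, d)))
  fst <- factor_scores(em, d, cs, k = 3)
  x <- cs$rotation[d$timepoint + 1, 1:3]
  for (i in seq_len(nrow(em))) {
    fit <- lm(em[i, ] ~ 0 + x)
    sm <- summary(fit)$coefficients
    expect_equal(unname(fst$coefficients[i, ]), unname(coef(fit)),
                 tolerance = 1e-8)
    expect_equal(unname(fst$p.values[i, ]), unname(sm[, 4]),
                 tolerance = 1e-8)
  }
  expect_identical(fst$df, nrow(d) - 3L)
  # standardization invariant
  expect_true(all(abs(colMeans(fst$scores)) < 1e-6))
  expect_true(all(abs(apply(fst$scores, 2, sd) - 1) < 1e-6))
  # residual degrees of freedom guard
  tiny <- em[, 1:4]
  expect_error(factor_scores(tiny, d[1:4, ], cs, k = 3),
               "residual degrees of freedom")
})

test_that("null factor scores are normal and respond monotonely to effect", {
  sim <- simulate_timecourse(sim_config(list(planted_block("flat", 20000)),
                                        seed = 51))
  fit <- tcpca(sim$expression, sim$design, require_significance = FALSE)
  expect_gt(suppressWarnings(
    ks.test(fit$scores$scores[, 2], "pnorm")$p.value), 0.01)
  expect_gt(suppressWarnings(
    ks.test(fit$scores$scores[, 3], "pnorm")$p.value), 0.01)

  mean_abs_f2 <- function(effect) {
    v <- vapply(1:8, function(s) {
      sim <- simulate_timecourse(sim_config(
        list(planted_block("sustained_increase", 50, effect),
             planted_block("flat", 2000)), seed = 100 + s))
      f <- tcpca(sim$expression, sim$design)
      mean(abs(f$scores$scores[1:50, 2]))
    }, numeric(1))
    mean(v)
  }
  expect_gt(mean_abs_f2(1.0), mean_abs_f2(0.5))
})

test_that("expected null fraction matches the normal tail", {
  expect_equal(expected_null_fraction(3.29, "two"),
               2 * pnorm(3.29, lower.tail = FALSE))
  expect_equal(expected_null_fraction(0, "two"), 1)
  expect_equal(expected_null_fraction(3.29, "one"),
               expected_null_fraction(3.29, "two") / 2)
  expect_error(expected_null_fraction(-1), "non-negative")
})

test_that("selection applies the inclusive cut-off and the filter", {
  f <- cbind(f1 = c(0, 0, 0, 0), f2 = c(3.29, 3.28, -4, 0),
             f3 = c(0, 0, 0, 5))
  p <- matrix(1e-6, 4, 3)
  fst <- fake_scores(f, p)
  sel <- select_probes(fst)
  expect_identical(sel$selected, c(TRUE, FALSE, TRUE, TRUE))    # >= inclusive
  expect_identical(sel$component, c(2L, NA, 2L, 3L))

  # significance filter removes high-p probes; off keeps them
  p2 <- p; p2[1, 2] <- 0.5
  sel2 <- select_probes(fake_scores(f, p2))
  expect_false(sel2$selected[1])
  sel3 <- select_probes(fake_scores(f, p2), require_significance = FALSE)
  expect_true(sel3$selected[1])

  # all below cut-off: empty selection
  sel4 <- select_probes(fake_scores(f / 10, p))
  expect_false(any(sel4$selected))
  expect_error(select_probes(fst, cutoff = -1), "cutoff")
  expect_error(select_probes(fst, alpha = 1.5), "alpha")
})

test_that("subgroups follow the sign rules with component-2 precedence", {
  f <- cbind(f1 = 0, f2 = c(-5, 5, 0, 0, 5), f3 = c(0, 0, 5, -5, 5))
  fst <- fake_scores(f)
  sel <- classify_subgroups(fst, select_probes(fst))
  expect_identical(sel$subgroup, c(1L, 2L, 3L, 4L, 2L))  # last: precedence

  un <- fake_scores(f, oriented = FALSE)
  expect_error(classify_subgroups(un, select_probes(un)), "oriented")

  none <- fake_scores(f / 100)
  seln <- classify_subgroups(none, select_probes(none))
  expect_true(all(is.na(seln$subgroup)))
})

test_that("annotation drops unannotatable probes and counts them", {
  f <- cbind(f1 = 0, f2 = c(5, 5, 5, 5, 0), f3 = 0)
  fst <- fake_scores(f)
  sel <- classify_subgroups(fst, select_probes(fst))
  ann <- data.frame(probe_id = sprintf("P%03d", 1:5),
                    gene_symbol = c("A", NA, "B", "", "C"),
                    stringsAsFactors = FALSE)
  res <- annotate_selection(sel, ann)
  expect_identical(res$genes$gene_symbol, c("A", "B"))
  expect_identical(res$n_unannotated, 2L)
  expect_true(all(res$genes$subgroup == 2L))

  expect_error(annotate_selection(sel, ann[-1, ]), "absent.*P001")

  allann <- ann; allann$gene_symbol <- LETTERS[1:5]
  res2 <- annotate_selection(sel, allann)
  expect_identical(res2$n_unannotated, 0L)
  expect_identical(nrow(res2$genes), 4L)
})
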