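# Shared fixtures: small designs and matrices built in code.

make_design <- function(n_tp = 6L, n_rep = 2L) {
  data.frame(
    sample_id = sprintf("T%d_R%d", rep(seq_len(n_tp) - 1L, each = n_rep),
                        rep(seq_len(n_rep), times = n_tp)),
    timepoint = rep(seq_len(n_tp) - 1L, each = n_rep),
    replicate = rep(seq_len(n_rep), times = n_tp),
    stringsAsFactors = FALSE)
}

make_matrix <- function(n_probes, design, seed = 1L, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * nrow(design), 7, sd), nrow = n_probes,
              dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                              design$sample_id))
  m
}

# Build a tc_scores object directly, for boundary/precedence tests that need
# exact score values.
fake_scores <- function(f, p = matrix(1e-6, nrow(f), ncol(f)),
                        oriented = TRUE) {
  structure(list(probe_id = sprintf("P%03d", seq_len(nrow(f))),
                 coefficients = f, scores = f, p.values = p,
                 sigma2 = rep(1, nrow(f)), df = 9L, k = ncol(f),
                 oriented = oriented),
            class = "tc_scores")
}

# Independent eigenvalue oracle: characteristic polynomial coefficients by
# the Faddeev-LeVerrier recursion, roots by polyroot().
charpoly_eigenvalues <- function(s) {
  n <- nrow(s)
  co <- numeric(n)
  mk <- s
  co[1] <- -sum(diag(mk))
  if (n > 1) for (k in 2:n) {
    mk <- s %*% (mk + co[k - 1] * diag(n))
    co[k] <- -sum(diag(mk)) / k
  }
  sort(Re(polyroot(c(rev(co), 1))), decreasing = TRUE)
}

# Independent hypergeometric oracle: exhaustive enumeration of all draws.
enum_hypergeom_p <- function(overlap, list_size, set_size, universe_size) {
  draws <- utils::combn(universe_size, list_size)
  mean(colSums(draws <= set_size) >= overlap)
}
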