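---
title: "Selecting temporal expression profiles with PCA factor scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting temporal expression profiles with PCA factor scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcpca)
```

## The model

`tcpca` targets a short, replicated expression time course: `T` time
points (six in the motivating design, weeks 0–5 of chondrogenic
differentiation of fetal mesenchymal stromal cells), `R` replicate arrays
per time point (two), and tens of thousands of probes measured on the
log2 scale. The analysis decomposes the probes-by-time-points matrix of
replicate means into orthonormal temporal profiles and asks, probe by
probe, how strongly each profile is expressed.

Formally, with `m_gt` the mean of probe `g` at time point `t`, the
`T × T` covariance matrix of the columns of `m` (centered across probes)
is eigendecomposed. Because between-probe level differences dwarf
temporal changes, the first eigenvector is essentially the constant
profile ("general level of expression"); the second is close to a
centered linear ramp (monotone change with time); the third to a
symmetric tent (transient mid-course deviation). Signs of eigenvectors
are arbitrary, so `orient_components()` fixes them deterministically:
component 1 to a positive mean, component 2 to a positive inner product
with the ascending time index, component 3 so its interior mean exceeds
its endpoint mean, and later components to a positive largest-magnitude
entry. Exact ties resolve towards +1 with a message. The map is
idempotent, so orienting twice changes nothing.

### Factor scores

For each probe the `T × R` per-sample values are regressed by ordinary
least squares on components 1..k (default `k = 3`) evaluated at the
sample's time point. Two numerical choices matter here:

* **No separate intercept.** Component 1 *is* (up to estimation error of
  order 1e-3) the constant profile, so an added intercept column would be
  near-collinear with it. The two near-parallel columns span a plane that
  also contains the tiny tilt direction of component 1 — typically the
  ramp — and projecting it out inflates the variance of the component-2
  coefficient by two orders of magnitude (we observed the coefficient SD
  grow from 0.18 to 1.84, collapsing recovery of planted trends to
  zero). With the components alone, the design matrix has exactly
  orthogonal columns under balanced replication (`X'X = R·I`), joint and
  marginal coefficients coincide, and the residual degrees of freedom are
  `n − k` (9 in the 6×2 design).
* **Unstandardized means by default.** The per-probe scaling to mean 0,
  SD 1 is available (`standardize = TRUE`, or `standardize_rows()`), but
  the covariance PCA runs on unstandardized means by default: the
  "general level" component only exists while between-probe level
  differences survive, and standardization is treated as a reporting
  transform. Both routes are exposed because the original description
  leaves the order unstated.

Each coefficient column is then standardized across probes to mean 0 and
SD 1 — the *factor scores*. Under pure noise a score is a linear
combination of Gaussians and hence standard normal, which anchors the
selection null: `expected_null_fraction(3.29, "two")` = 0.1%, one tail
0.05%.

### Selection, significance filter, subgroups

A probe is selected when `max(|f2|, |f3|) ≥ 3.29` (inclusive; component 1
never triggers selection). Replication gives every coefficient a
two-sided t-test against zero with `n − k` df; with
`require_significance = TRUE` (default) the *triggering* coefficient must
also reach `p < 0.05`. Testing only the triggering coefficient is the
minimal reading of a "5% significance filter" on the selected score; the
filter can only shrink the selection, never move a probe between
subgroups. Subgroups are assigned with component-2 precedence
(`f2 ≤ −c` → 1, `f2 ≥ c` → 2, else `f3 ≥ c` → 3, `f3 ≤ −c` → 4), which
makes them disjoint and exhaustive over the selection — the printed
subgroup counts of the motivating study (146/105/49/15) indeed sum to its
printed total (315). Probes without a gene symbol are discarded from the
gene-level table and counted (`annotate_selection`), as in that study
(83 of 315).

## What the generator emulates — and what it does not

`simulate_timecourse()` draws, per probe, a baseline level
`N(baseline_mean, baseline_sd²)` shared by all of the probe's samples (this
reproduces the dominant level component), adds the block's expected
temporal profile, and adds independent `N(0, noise_sd²)` noise per
sample. Defaults state the assumed world once:

* `n_timepoints = 6`, `n_replicates = 2` — the replicated weekly design;
  fewer than 2 replicates is an error because the significance filter
  needs replication.
* `baseline_mean = 7`, `baseline_sd = 2` log2 units — a typical
  mid-intensity level and between-gene spread for expression arrays.
* `noise_sd = 0.25` log2 units — a realistic replicate-array noise scale;
  the original arrays' noise magnitude is unpublished, so this is a free
  parameter of the stated world, not an estimate of that dataset.
* `frac_unannotated = 0.25` — matches the ~26% annotation loss (83/315)
  reported in the motivating study.

Profile shapes: sustained classes are linear in the time index (strictly
monotone in expectation); transient classes are a symmetric tent over the
interior time points, zero at both endpoints, apex mid-course (weeks 2–3
in the 6-point design). Every non-flat shape is scaled so that the
**centered L2 norm of the expected profile equals `effect_size`** and
anchored at zero at the first time point. This convention makes
`effect_size` directly comparable across classes and to `noise_sd`: it is
the expected regression amplitude on the matching unit-length component,
so the expected factor score of a planted probe is roughly
`effect_size / (noise_sd · sqrt(2/R) · s)` with `s` the score SD across
probes. For the 6-point tent the centered norm coincides with the
peak-to-trough range; for the sustained ramp the peak-to-trough range is
`effect_size / sqrt(0.35) ≈ 1.69 × effect_size`. (Scaling the ramp by its
range instead would make an `effect_size` of four noise SDs sit almost
exactly *on* the 3.29 cut-off — mean score ≈ 3.2 — and no parameter
choice could then meet a 95% recovery property; the amplitude convention
keeps the documented recovery behaviour coherent.)

The generator does **not** emulate probe-level PM/MM intensities, CEL
files, normalization artefacts, correlated noise between replicates, or
many-to-one probe–gene maps. A green recovery test therefore establishes
that the selection machinery recovers planted temporal structure under
Gaussian replicate noise — not that any specific biological dataset is
reproduced.

Recovery calibration, chosen a priori by power analysis and then frozen:
with planted effect four times the noise SD, 400/400/200/200 planted
probes among 100,000 flat ones, the expected per-class misassignment is
1.5–2.3%, so each class clears a 95% recovery bar with ~99.9%
probability; flat probes are selected at ~0.1–0.2%. The sustained classes
need more planted probes than the transient classes so that the ramp and
tent eigenvalues separate — with exactly equal planted energy the two
eigenvalues tie and the eigenvectors may rotate arbitrarily within their
subspace.

## Fold changes, reference comparison, enrichment, qPCR

* `fold_change()` computes `FC(g,t) = 2^(mean_t − mean_baseline)` from
  replicate means (ratio of means for linear-scale input via
  `scale = "linear"`); the baseline column is exactly 1.
  `threshold_fold_change()` applies an inclusive cut-off (default 3.29)
  and returns disjoint up/down lists; `export_network_list()` writes the
  deduplicated one-symbol-per-line file that protein-network services
  accept.
* `compare_to_reference()` is a gene-level stand-in for the original
  probe-level mixed model (which needs raw CEL data and proprietary
  software): a pooled-variance two-sample t-test per gene with Bonferroni
  control at `alpha = 0.05`. Note the power arithmetic: at 3 vs 3
  replicates the Bonferroni critical value over 5,000 genes is ~28
  standard errors (df = 4), so even a five-SD shift is rarely declared;
  the power tests use 8 replicates per group where the analytic power is
  0.98.
* `enrich()` is a desk-scale stand-in for the web-service pathway search:
  the exact hypergeometric upper tail per set, against a universe that
  defaults to all annotated genes on the array (the array-background
  concept), Bonferroni by default (mirroring the study's stated testing
  policy), BH and the conservative EASE variant (overlap reduced by one)
  as options. Exact-test p-values are *discrete*: with small expected
  overlaps they are markedly conservative, so the null-calibration
  experiment uses wide margins (universe 20,000, sets of 5,000, lists of
  4,000 — maximal point mass ~0.016) where near-uniformity actually
  holds. Which statistic and background the original web service used in
  2012 is not recorded; the plain exact test is the default.
* `ddct_fold_change()` implements 2^−ΔΔCt with a single explicit
  reference gene per run and an explicit calibrator sample. The
  motivating study cites two housekeeping genes in different places (B2M
  for the ΔΔCt analysis, GAPDH in a figure legend), so the reference is a
  required, visible parameter rather than a hidden default; a base-10 log
  is reported alongside for plotting. Amplification-efficiency correction
  is out of scope.

## Degenerate inputs and numerical conventions

Zero-variance rows are rejected (standardization and PCA are undefined);
missing values are rejected rather than imputed — the designs this
package addresses are complete, and imputation would add unvalidated
behaviour. All cut-off comparisons are inclusive (`≥`). Orientation ties
resolve to +1. Score standardization uses the `n − 1` SD. Writers emit
17-significant-digit TSV so matrices round-trip bit-identically.

## Known limitations

The significance filter tests only the triggering coefficient, without
multiplicity correction, by design. The four-way classification presumes
oriented components and a design where level ≫ trend ≫ noise; with fewer
than ~50 probes the score standardization itself becomes noisy. The
enrichment test treats gene sets as unstructured; topology-aware pathway
analysis is out of scope, as are live queries to annotation or network
web services — gene lists are exported in the format those services
accept instead.
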