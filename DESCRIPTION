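Package: tcpca
Title: Time-Course Expression Profile Selection by Principal Component
    Factor Scores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects temporally regulated probes from replicated
    time-course expression microarray experiments. A principal component
    analysis of the time-point covariance matrix yields orthonormal
    temporal profiles; per-probe factor scores are obtained by regressing
    the replicated array values on the leading components, outlying
    probes are selected with a 3.29 standard-deviation cut-off and a
    replicate-based significance filter, and selected probes are
    classified into four temporal profile subgroups. Companion tools
    compute fold-change gene lists against a baseline time point,
    Bonferroni-corrected two-sample differential expression against a
    reference tissue, hypergeometric gene-set over-representation with
    GMT input, and 2^-ddCt quantification of qPCR plates. A synthetic
    data generator emulating a replicated six-time-point design provides
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
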