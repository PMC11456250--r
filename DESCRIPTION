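Package: cziptf
Title: Consensus Zero-Inflated Poisson Tensor Factorization for Multi-Sample Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian non-negative CP (Candecomp/Parafac) decomposition of count
    tensors under a zero-inflated Poisson observation model, fitted by stochastic
    variational inference, together with a consensus meta-analysis (C-ZIPTF) that
    stabilizes factors across random restarts. Includes rank-selection diagnostics
    (explained variance, cophenetic correlation, silhouette), a pseudobulk tensor
    builder for multi-sample multi-condition single-cell RNA-seq counts, synthetic
    data generators for zero-inflated low-rank tensors and Splatter-style
    single-cell counts, and tools to score recovered gene expression programs
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
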