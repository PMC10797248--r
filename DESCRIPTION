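Package: gwasdecomp
Title: Principal and Independent Genomic Components from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes multi-trait genome-wide association study (GWAS)
    summary statistics into principal and independent genomic components.
    Per-trait effect sizes (raw betas or standard-error scaled z-values) are
    harmonized and stacked into a traits-by-SNPs matrix, reduced to
    approximately independent variants by LD pruning and min-p clumping, and
    decomposed by uncentered singular value decomposition followed by
    fixed-point negentropy maximisation (FastICA-style) rotation. Includes
    cross-sample component reproducibility statistics with a univariate GWAS
    benchmark, Fisher-exact overlap tests of thresholded loadings, normal-CDF
    loading significance for Manhattan-style summaries, a deterministic t-SNE
    embedding of trait loadings, and a synthetic paired-GWAS simulator with
    planted latent genomic factors, block LD and MAF-dependent standard
    errors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    cluster
Config/testthat/edition: 3
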