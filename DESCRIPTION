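Package: persexpr
Title: Evaluation of Personal-Genome Gene Expression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for evaluating sequence-based gene expression
    predictors on personal genomes. Builds phased per-haplotype input
    sequences around gene transcription start sites from a reference
    genome and phased SNV genotypes, runs pluggable predictors with
    standard prediction-aggregation rules (forward/reverse-complement
    averaging, small sequence shifts, binned-track TSS windows,
    haplotype averaging, cross-model ensembling), and quantifies
    cross-gene versus cross-individual rank-correlation performance,
    an elastic-net cis-genotype baseline, and direction-of-effect
    classification accuracy for fine-mapped QTL variants. Includes a
    synthetic-cohort generator with known cis-regulatory truth so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
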