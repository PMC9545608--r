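Package: corticlass
Title: Conserved and Region-Specific Class-Relevant Genes in Neocortical
    Neuronal Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns circuit-related genes to major neocortical neuronal
    classes from class-labeled single-cell expression counts, and categorizes
    each gene's class relationship as conserved across two cortical regions
    (ALM and VISp), specific to one region, or divergent. Implements
    log-normalization, ordered pairwise Wilcoxon rank-sum differential
    expression with a log fold-change pre-filter and Bonferroni correction,
    gene-set (GMT) filtering and risk-gene flagging, the region-specificity
    collapse of analogous cross-region comparisons, class-set consistency
    logic to identify class-relevant genes (including cross-region
    reconciliation and region-bias queries), summary matrices for chord
    diagrams and stacked-bar counts, and a negative-binomial synthetic data
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
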