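Package: triomics
Title: Integrated Expression, CpG Island Methylation and Copy Number
    Analysis for Two-Group Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of an integrated deep-sequencing
    analysis of breast cell lines: empirical-Bayes moderated t
    differential expression on pseudocounted log2 reads-per-million,
    Storey q-value FDR, correlation-distance cluster stability by noise
    perturbation, reduced-representation bisulfite methylation calling
    against an in-silico MspI fragment reference with 3-letter
    alignment, read-depth copy-number segmentation with recursive
    t-test splitting, phenotype-permutation gene set enrichment, panel
    (NanoString-style) normalization, and the cross-layer integration
    that yields methylation/expression and CNA/expression gene
    signatures.  A synthetic-data module generates a toy genome,
    bisulfite reads, DNA tags and negative-binomial counts with known
    ground truth so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
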