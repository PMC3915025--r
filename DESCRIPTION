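Package: multidiv
Title: Comparative Multigene Evolutionary Distance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of evolutionary divergence across
    linked marker genes. Computes masked pairwise evolutionary distances
    (uncorrected and Jukes-Cantor corrected) from aligned nucleotide
    sequences, builds neighbor-joining trees, and performs gene-versus-gene
    divergence regression with clade partitioning, slope-homogeneity
    (ANCOVA) F-tests, detection of horizontal gene transfer as discontinuity
    in divergence plots, and 16S-versus-marker divergence-threshold
    analysis. Includes collection-level sequence characterization (fragment
    lengths, start/stop positions in reference coordinates, primer-trimming
    diagnostics, G+C content and bimodality, genome-versus-gene G+C
    regression) and a synthetic multigene data generator (F81 simulation on
    two-clade phylogenies with lineage-specific rates and grafted transfer
    events) that emits machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
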