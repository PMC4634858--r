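Package: tmtintegrate
Title: Proteogenomic Integration of Isobaric TMT Proteomics and Microarray
    Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantitative proteogenomics on 6-plex tandem mass
    tag (TMT) peptide data with matched microarray gene expression. Implements
    peptide-level quality filtering (posterior error probability, decoy and
    contaminant flags, missingness), log2 transformation, iterative
    rank-invariant reference normalization, all-possible-protein peptide
    mapping with one-step Tukey biweight rollup to protein intensities, Welch
    two-sample differential testing with fold-change significance calls,
    correlation-distance complete-linkage clustering, probe-to-protein
    matching, gene-protein concordance statistics, and cross-study dataset
    comparison. Includes a seeded synthetic-data generator emulating 6-plex
    TMT peptide tables and matched arrays with known ground truth, so every
    stage has a recovery target.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
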