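Package: amplitax
Title: Amplicon Meta-Barcoding Taxonomic Binning and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for taxonomic binning of amplicon meta-barcoding
    reads (16S rRNA hypervariable regions, fungal ITS1) and for
    benchmarking such classifiers. Implements NCBI-dialect taxonomy
    loading and guide-tree construction, degenerate-primer in-silico PCR
    and truth-labeled MiSeq-like paired-read simulation, quality-aware
    paired-end merging with trimming and dereplication, multi-criterion
    alignment-hit filtering (identity, query coverage, bitscore
    tolerance, taxonomic-path completeness), penalty-minimizing
    taxonomic assignment on a reference guide tree with a lowest-common-
    ancestor special case, per-rank macro-averaged sensitivity and
    specificity evaluation, and a reference-database depletion
    experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    stats,
    utils,
    tools
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
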