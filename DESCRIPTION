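Package: tnpquant
Title: Transposase Abundance and Expression in Size-Fractionated
    Metagenomes and Metatranscriptomes
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies insertion-sequence transposases on assembled
    contigs from translated-search hits using footprint designation,
    iterative highest-score resolution and e-value and ORF-coverage
    filters; normalizes transposase read counts per bacterial reads, per
    genome (via single-copy marker genes), per taxon and per IS family;
    computes transcript-to-gene expression ratios between matched
    metatranscriptome and metagenome samples; and provides the rank-sum
    and linear-model contrasts used for size-fraction and regional
    comparisons. Includes a synthetic-community generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
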