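Package: segexplore
Title: Exploratory Analysis of Genomic Segmentations
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Summary statistics and visualizations for labeled genomic
    segmentations: segment length distributions, mono- and dinucleotide
    frequencies, label transition matrices, aggregation enrichment around
    point features, across regions and along idealized gene components,
    overlap precision-recall against annotations, pairwise label edit
    distances, per-label signal means and variances, flattening of several
    interval sets into combination labels, nearest-feature distances, and
    an HTML report collating the outputs. Segmentations and annotations are
    read from BED and GFF, gene models from GTF, genomes from FASTA and
    continuous signal from bedGraph or wiggle. A fixture generator produces
    synthetic genomes, segmentations, gene models and signal tracks with
    known ground truth.
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'flatten.R'
    'summaries.R'
    'aggregation.R'
    'comparisons.R'
    'report.R'
    'fixtures.R'
    'cli.R'
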