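Package: clipmod
Title: Crosslink Truncation Site Calling and m6A/m6Am Classification for
    iCLIP and miCLIP Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-nucleotide analysis of iCLIP-style CLIP-seq libraries:
    conversion of aligned reads to per-nucleotide crosslink-induced
    truncation counts, binomial calling of significant truncation sites
    (CITS) with genome-wide FDR control, control-library filtering and
    replicate merging, classification of anti-m6A miCLIP truncation peaks
    into m6A (DRACH-anchored) and m6Am (5'-proximal adenosine) sites,
    length-standardized metagene profiles and peaks-per-kilobase feature
    distributions, anchored signal-density profiles with matched
    random-site null models and rank-test quantification, peak-overlap
    statistics, per-site count matrices with median-of-ratios
    normalization and group comparisons, and a fully seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'truncations.R'
    'anchor.R'
    'clipmod-package.R'
    'counts.R'
    'metagene.R'
    'modsites.R'
    'simulate.R'
    'pipeline.R'
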