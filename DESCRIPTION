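Package: intervanno
Title: Flexible Annotation of Genomic and Transcriptomic Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a queryable feature database from GTF/GFF3 genome
    annotations and annotates intervals given in genomic or spliced
    transcript coordinates with overlapping genes, transcripts and child
    features (CDS, UTRs), relative transcript regions derived from
    quartile rules, and closest-gene information for intergenic
    intervals. Reads BED, VCF and arbitrary column-based text tables with
    user-declared columns and 0- or 1-based conventions, appends
    annotation columns without altering the original content, and reports
    summary statistics of the assigned features. Includes a deterministic
    synthetic-annotation generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
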