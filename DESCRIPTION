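Package: ppscan
Title: Promoter Class Discovery and Genome-Wide Promoter Scanning with
    Dinucleotide Position-Weight Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistically calibrated classes of plant promoter
    sequences from annotated gene starts and scans whole genomes for
    potential promoter sequences (PPS). Promoter regions (-499..+100
    around the annotated start) are filtered, classified iteratively into
    disjoint classes, and each class is summarised by a 16-row dinucleotide
    position-weight matrix normalised to fixed first and second moments.
    Genomes are scanned by local profile-sequence dynamic programming with
    indels; significance is measured as a Z score against a shuffled-sequence
    Monte-Carlo null. Includes complete-linkage clustering of class matrices,
    a two-proportion U test for transcriptome support, strand/mirror control
    scans, a flat-file PPS database exporter (TSV/BED/GFF3), and a seeded
    synthetic-genome generator with planted promoter classes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
NeedsCompilation: yes
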