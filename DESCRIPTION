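Package: exograph
Title: Reference-Free Exon and Splice Graph Prediction from a
    Transcriptome and Whole-Genome Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts exon sequences and the splice graph of an assembled
    transcriptome using raw whole-genome sequencing reads instead of a
    reference genome.  Reads are baited against a Bloom filter of the
    transcriptome, surviving reads populate a cascading Bloom filter whose
    last level holds solid (frequent-enough) k-mers, and each transcript
    is scanned for runs of solid k-mers to call exon intervals; k-mers
    spanning intron-exon boundaries are absent from genomic reads, which
    is the signal the method exploits.  Results are written as a GFA1
    splice graph (exons as segments, boundaries as links, transcripts as
    paths) and as FASTA.  Includes annotation-recovery evaluation against
    GFF3 at reciprocal-overlap thresholds, and a deterministic simulator
    of toy genomes, transcriptomes and error-bearing short reads for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
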