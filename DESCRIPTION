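Package: minisplice
Title: Minigene Splice Assay Quantification from Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing minigene splicing assays read out by long-read
    (nanopore) cDNA amplicon sequencing. Provides coordinate algebra between
    HGVS-style c. positions with intronic offsets, genomic positions on a
    stranded reference, and construct-local positions; position-frequency-matrix
    scoring of donor and acceptor splice sites; exonic splicing enhancer and
    silencer hexamer profiling of reference versus variant alleles; extraction
    of splice-junction chains from spliced alignments; junction correction
    against a splice-site registry; transcript classification and relative
    abundance quantification with condition comparison; pseudoexon inclusion
    estimation from short-read split-read counts; antisense oligonucleotide
    candidate evaluation; and a fully synthetic data generator so that every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
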