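Package: tillcall
Title: Population-Scale EMS Mutation Discovery for TILLING by Exome Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mutation-discovery stack for TILLING (Targeting Induced Local
    Lesions in Genomes) populations sequenced by exome capture. Builds a
    coverage-driven exome reference from one or more genome assemblies
    (high-coverage region extraction, flanking, merging, contig excision with
    provenance), removes PCR duplicates from coordinate-sorted paired-end
    alignments, calls EMS-induced point mutations and small deletions from a
    multi-sample text pileup using population-scale uniqueness and coverage
    criteria, predicts zygosity from mutant-allele fractions, summarises the
    mutation spectrum (CG-to-TA fraction, het:hom ratio, mutations per Mbp),
    and exports an SQLite/CSV mutation table with flanking sequences. A
    synthetic M2-population simulator generates reference, truth table,
    multi-sample pileup and duplicated read pairs so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    stringi,
    jsonlite,
    Biostrings,
    IRanges,
    DBI,
    RSQLite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics,
    yaml
Config/testthat/edition: 3
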