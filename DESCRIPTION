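Package: pfpindex
Title: Prefix-Free-Parsing BWT Construction and the r-Index for Repetitive Text Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the Burrows-Wheeler transform, the suffix array, and the
    run-boundary suffix-array sample of a text from its prefix-free parse, and
    assembles them into an r-index: a run-length compressed FM-index that
    answers exact count and locate queries over highly repetitive collections
    such as pan-genomes. Includes FASTA ingestion with DNA-alphabet filtering
    and optional reverse-complement indexing, a versioned on-disk index
    container, brute-force oracles for validation, and a synthetic
    pan-genome collection generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    optparse
Config/testthat/edition: 3
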