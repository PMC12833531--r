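Package: slipscreen
Title: Detection and Mitigation of +1 Ribosomal Frameshift Slippery Sites
    in Therapeutic mRNA Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens mRNA coding sequences for codon-aligned slippery
    motifs (UUUU, UUUC, AAAG) at which N1-methylpseudouridine-modified
    transcripts can undergo +1 ribosomal frameshifting, emulates the
    frameshift by single-base deletion to predict the chimeric protein
    product at each site, exports the putative peptides for external
    homology screening (e.g. BLASTx), and synonymously recodes the
    slippery codons to remove the sites while provably preserving the
    encoded protein. Includes a synthetic coding-sequence generator with
    planted sites and an independent brute-force scanning oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Biostrings,
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Transcription, QualityControl, Translation
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
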