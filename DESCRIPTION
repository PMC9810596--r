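Package: mitostall
Title: Codon-Resolution Mitoribosome Profiling and Stall Detection at
    Non-Canonical Mitochondrial Stop Codons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for codon-resolution analysis of mitochondrial ribosome
    profiling data on the circular human mitochondrial genome. Models the 13
    mitochondrial open reading frames and the vertebrate mitochondrial genetic
    code (UGA as tryptophan, AUA/AUU as start codons, AGA/AGG as non-canonical
    stop codons without cognate tRNAs), processes ribosome-protected fragments
    from raw FASTQ (3' adapter trimming, footprint length filtering, exhaustive
    circular-genome mapping), assigns A-site codons with a fixed 5' offset,
    builds per-sample codon count tables, and quantifies mitoribosome stalling
    at transcript ends: per-transcript relative occupancy, gene size factors,
    terminal-window occupancy and fold changes versus a reference sample, codon
    identity profiles, and detection of queued ribosomes one footprint length
    upstream of a stall. A synthetic footprint generator with per-read ground
    truth makes every pipeline stage verifiable without sequencing data, and
    small helpers implement the arithmetic of in vitro peptide release assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
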