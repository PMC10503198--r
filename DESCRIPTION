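Package: flanklift
Title: Chain-File-Free SNP Lift-Over Between Genome Assembly Versions
Version: 0.1.0
Authors@R:
    person("Ottawa", "Genomics Tools", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Projects single-nucleotide variants from one version of a genome
    assembly onto another without a chain file.  Each SNP is wrapped in a
    flanking "parent" window that is aligned to the whole target assembly by a
    seed-chain-extend aligner; the single-base "child" coordinate is deduced
    by walking the alignment's coordinate map.  Lifts are repeated at several
    flank lengths and only SNPs projected to the identical location at every
    length are retained.  Includes transition classification (chromosome
    changes, unanchored-scaffold anchoring), strand policies with allele
    complementation, per-chromosome SNP density reports, a minimal
    transcript-relative variant effect classifier, and a synthetic
    assembly-update simulator with an exact truth map so the entire pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
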