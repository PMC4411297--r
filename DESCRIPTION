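Package: cuedit
Title: Differential C-to-U RNA Editing Detection from RNA-Seq Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterization of differential C>U (and A>I) RNA
    editing sites from paired RNA-seq base-call pileups. Implements a
    strand-aware samtools-mpileup text parser, a per-site candidacy and
    editing-level filtering cascade, a paired beta-binomial (inverted
    beta-binomial) differential test with Storey bootstrap q-values,
    mapping-artifact and strand-bias post-filters, sequence and secondary
    structure context analysis (tetramer motif classes, relative-entropy
    logos, palindromic flanks, base-pair-maximization folding), targeted
    editing quantification (Sanger peak heights, per-ORF pileup scans), and a
    synthetic paired-pileup generator with planted editing sites so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
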