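Package: ampminer
Title: Mining Defensin, Ovodefensin and Cathelicidin Genes from Genome
    Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects antimicrobial peptide (AMP) genes of the beta-defensin,
    beta-ovodefensin and cathelicidin families in genome scaffolds and
    candidate peptide sets.  Provides six-frame translation with genomic
    coordinate mapping, a cysteine-spacing motif scanner with configurable
    gap ranges, a peptide physicochemical property engine (average molecular
    weight, fixed-value net charge, Henderson-Hasselbalch isoelectric
    point), a cathelicidin precursor classifier based on the cathelin-domain
    cysteine census and cleavage-motif search, gene-cluster construction
    with flanking-marker labelling and locus naming, and a synthetic-genome
    generator with planted genes and certified decoys for end-to-end
    evaluation.  Ships the published Komodo dragon (Varanus komodoensis)
    defensin, ovodefensin and cathelicidin peptide sets as fixtures together
    with their published property tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
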