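Package: ampedit
Title: CRISPR Amplicon Editing-Outcome Analysis with Microhomology-Aware
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR-Cas editing outcomes from deep amplicon
    sequencing. Locates protospacers and predicted double-strand-break
    positions for blunt-cutting (SpCas9) and staggered-cutting (AsCas12a)
    nucleases, enumerates microhomology pairs flanking the cut and the
    MMEJ deletion alleles they predict, aligns reads to the reference
    amplicon with an affine-gap Needleman-Wunsch aligner, calls
    left-normalized indels, and classifies every allele into a five-way
    repair-outcome taxonomy (WT/substitution, insertion, on-position
    deletion with or without junction microhomology, off-position
    deletion). Includes a PAM-constrained mismatch off-target scanner
    with exon/intron/intergenic annotation and a deterministic paired-end
    MiSeq-style amplicon read simulator, so every pipeline stage can be
    validated round-trip without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
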