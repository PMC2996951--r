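Package: trnanchor
Title: tRNA-Anchored Degenerate Primer Design and COI Barcode Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recovering the mitochondrial COI barcode region via
    primers anchored in conserved tRNA genes upstream of the target. Surveys
    gene arrangements upstream of COI across annotated mitogenomes, selects a
    positionally stable forward-oriented anchor gene, aligns anchor sequences
    (center-star multiple alignment), partitions them into homogeneity groups,
    derives IUPAC degenerate consensus primers, predicts amplification success
    in silico from primer-template mismatch profiles with a 3'-proximal failure
    rule, and quality-controls recovered barcode reads: upstream-tRNA trimming,
    canonical and non-canonical translation initiation-codon calling under the
    invertebrate mitochondrial code, NUMT screening (frameshifts, internal stop
    codons), and amino-acid indel detection against a reference profile. A
    seeded simulator generates annotated mitogenomes and reads with planted
    ground truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
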