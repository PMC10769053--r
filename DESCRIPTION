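Package: longsv
Title: Validation and Genotyping of Structural Variants from Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Validates candidate structural variants (deletions, insertions,
    inversions) against long-read alignments. For each candidate the package
    screens spanning reads, extracts read-level support from CIGAR indel
    signatures and split (supplementary) alignments, and classifies the call
    as homozygous, heterozygous, or false from the fraction of supporting
    reads; when a listed SV is false but the locus carries a different
    variant, a corrected length is reported. Includes a deterministic
    simulator that writes ground-truth SAM alignments over a synthetic
    repeat-bearing reference, a false-call generator for benchmarking, and
    recall/precision/F1 scoring against a truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
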