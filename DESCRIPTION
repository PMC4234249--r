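Package: smvtools
Title: Somatic Microsatellite Variation from Tumor-Only Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Catalogue microsatellite (short tandem repeat) loci from a
    reference sequence, call haplotype and non-haplotype ("minor") alleles
    per locus from aligned short reads without a matched normal, classify
    minor alleles as SNP, expansion or contraction, and compute sample-level
    somatic microsatellite variation summaries, pairwise concordance with a
    randomization null, 1-Mb hotspot statistics and exon/gene reports.
    Includes a paired-end read simulator with planted diploid genotypes and
    subclonal minor alleles for error characterization and end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
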