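Package: editdiff
Title: Differential A-to-I RNA Editing Analysis from Aligned RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo detection of candidate adenosine-to-inosine (A-to-I) RNA
    editing sites from coordinate-sorted RNA-Seq alignments without matched
    genomic DNA, using per-position base-distribution pileups under strict
    read, mapping-quality and base-quality filters. Candidate sites are
    filtered against a genomic SNV catalog (VCF), a known-editing-site catalog
    and protein-coding annotation, then compared between two cohorts site by
    site with two-sided Fisher exact tests and Benjamini-Hochberg false
    discovery rate correction, and cohort-wide with a library-size-normalized
    editing-burden rank-sum comparison. Includes a fully seeded synthetic
    cohort simulator (reference, annotation, catalogs and aligned reads with
    planted editing, SNVs and sequencing error) so the whole pipeline can be
    exercised end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    graphics,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
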