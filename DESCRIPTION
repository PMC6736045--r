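Package: mitolineage
Title: Intraspecific Mitogenome and K-Region Diversity Analysis for Fission Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing intraspecific diversity of circular-mapping
    mitochondrial genomes and of the recombination-repressed K-region of the
    fission yeast nuclear genome. Canonicalizes circular contigs (terminal
    overlap trimming, rotation to a reference anchor, strand fixing), builds
    bi-allelic segregating-site matrices with multi-nucleotide variant merging,
    classifies pairwise sequence differences and reference errors, constructs
    neighbor-joining p-distance trees with bootstrap support and midpoint
    rooting, assigns clades and subclades, fits a haploid two-component
    ancestry mixture by EM, scans for inter-clade mosaic (recombinant)
    genomes, analyzes intron presence-absence polymorphism and LAGLIDADG
    intron-encoded-protein features, and performs mutation-rate-calibrated
    strict-clock divergence dating. Includes a forward simulator of two
    diverged lineages with full ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    BiocGenerics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
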