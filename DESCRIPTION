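Package: phyloHGT
Title: Phylogenomic Detection and Verification of Host-to-Parasite
    Horizontal Gene Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects horizontal gene transfer (HGT) between a parasitic
    plant and its host from per-cluster gene trees, using
    bootstrap-supported sister-group classification against the accepted
    species tree, with control-taxon background rates and a bootstrap
    threshold sweep. Verifies genomic integration of candidate transfers
    by exact 25 bp read-fragment matching of genomic DNA reads onto
    assembled transcripts, including split-read detection of GT..AG
    spliceosomal introns and parasite-host sequence divergence.
    Quantifies transcript expression by overlap-window read-count
    normalization and RPKM, and tests convergence of coding properties
    (nucleotide, dinucleotide and codon frequencies) toward the host
    genome with chi-squared profile distances, an exact binomial test and
    an expression-affinity rank correlation. Ships a synthetic-data
    generator with planted ground truth (grafted HGT tips, codon-biased
    sequences, planted introns, error-free reads) so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Phylogenetics, Genetics, Software, Transcriptomics
RoxygenNote: 7.3.3
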