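Package: RFLfinder
Title: Identification and Characterisation of Restorer-of-Fertility-Like
    PPR Genes in Genomic Sequence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for cataloguing restorer-of-fertility-like
    (RFL) pentatricopeptide repeat (PPR) genes directly from genomic DNA.
    Extracts open reading frames from six-frame translations, scans them with
    position-specific scoring profiles for 35-amino-acid P-class PPR motifs
    and tiles non-overlapping motif chains by dynamic programming, then
    isolates the RFL subfamily by three independent strategies (greedy
    identity clustering, orthogroup graph clustering with Markov clustering,
    and neighbor-joining clade extraction anchored on reference RFLs) and
    compares them in a consensus report. Downstream analyses cover genomic
    cluster organisation of RFL loci, amino-acid combination statistics at
    PPR motif positions 5 and 35 with PPR-code RNA target prediction, and
    motif-level duplication/deletion/insertion/transposition histories
    between paralogous architectures. A synthetic genome generator with full
    ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Phylogenetics,
    Clustering, MotifDiscovery
RoxygenNote: 7.3.3
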