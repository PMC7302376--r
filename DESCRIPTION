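Package: linkhap
Title: Polyploid Haplotype Assembly from Barcoded Linked Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles the K haplotypes of a polyploid genome from
    barcode-tagged linked short reads (10X Chromium style synthetic long
    reads).  Haplotype-informative allele calls are extracted from aligned
    reads and heterozygous SNPs, merged per barcode, deconvolved into
    molecule-specific fragments by one-dimensional mean-shift clustering,
    and partitioned into strongly connected fragment components by
    recursive normalized-cut bipartitioning.  Each component is phased by a
    max-K-cut semidefinite relaxation solved with a dual augmented
    Lagrangian scheme, followed by randomized rounding and majority-vote
    consensus.  Includes a fragment-level linked-read simulator and
    evaluation by reconstruction rate, vector error rate, and the minimum
    error correction (MEC) score.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
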