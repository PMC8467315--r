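Package: ceoseq
Title: Simulation and Quantification of Cas12a-Based Target Enrichment
    Nanopore Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Cas12a (Cpf1) negative-selection target enrichment
    followed by Oxford Nanopore sequencing, applied to long GC-rich
    repetitive loci such as the silkworm fibroin heavy-chain gene (FibH).
    Provides TTTV-PAM guide discovery with a mismatch-bounded off-target
    census, derivation of enrichment regions from paired guides, an
    in-silico twin of the dephosphorylation / Cas12a cleavage / adapter
    ligation / sequencing protocol over a synthetic FibH-like repetitive
    locus, per-region coverage and enrichment-fold quantification,
    tandem-repeat motif census with repetitive/amorphous domain
    segmentation, and aggregation of per-read CpG methylation calls into
    per-site and per-motif methylation frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
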