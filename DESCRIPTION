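Package: metallominer
Title: Rule-Based Detection of NRP Metallophore Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of non-ribosomal peptide (NRP) metallophore
    biosynthetic gene clusters (BGCs) in annotated bacterial genomes. A small
    boolean rule language over calibrated profile-HMM domain hits is parsed and
    evaluated with gene-scoped (cds) and region-scoped semantics, candidate BGC
    regions are assembled around NRPS anchor genes and flagged for contig-edge
    completeness, and each region is classified three ways: by chelator
    biosynthesis genes, by a two-of-three siderophore transporter criterion,
    and by their either/or ensemble. Includes per-profile bitscore cutoff
    calibration, precision/recall/F1 benchmarking against curated labels,
    chelator-combination censuses, and a deterministic synthetic-genome
    generator with planted clusters and ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
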