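Package: damchic
Title: Dual-Modality Single-Cell DamID and ChIC Processing and Retrospective Chromatin Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes plate-based single-cell libraries that combine cumulative
    DamID (m6A footprints at GATC motifs, recording past chromatin states) with
    antibody-directed MNase ChIC cuts (recording present states) in the same cell.
    Provides in silico read separation by sequence context, UMI deduplication with
    ploidy-aware counting, allele assignment, observed-over-expected normalization
    against in silico GATC mappability or an H3 control, lamina-associated-domain
    calling, contact-frequency statistics, a margin-preserving matrix permutation
    null for Jaccard co-occurrence, a two-species kinetic model for latent-time
    ordering of domains, change-point anchor detection, kNN cell-cycle phase
    enrichment and X-inactivation cell classification. A synthetic-data generator
    supplies ground truth (toy genomes, reads, occupancy matrices and kinetic
    trajectories) for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    minpack.lm,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'damchic-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'simulate-kinetics.R'
    'dynamics.R'
    'cellstate.R'
    'simulate-genome.R'
    'simulate-reads.R'
    'readproc.R'
    'normalize.R'
    'domains.R'
    'io.R'
    'similarity.R'
    'simulate-occupancy.R'
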