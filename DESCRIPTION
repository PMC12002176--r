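Package: ectopicgc
Title: Affinity Maturation, Polarization, and Clonal Sharing Analysis for Ectopic Germinal Centers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare ectopic (e.g. lung) germinal centers with
    conventional lymph-node germinal centers. Implements W33L affinity-mutation
    calling and replacement/silent mutation counting from Sanger reads of the
    VH186.2 heavy-chain variable region, a germinal-center polarization
    fraction and cell-density statistics from imaging-derived cell coordinates,
    and paired-junction B-cell clonotype clustering with cross-tissue and
    GC-to-memory sharing statistics. A seeded synthetic-data module generates
    ground-truthed reads, point patterns, and repertoires so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    mgcv,
    dplyr,
    tibble,
    tidyr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    seqinr,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
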