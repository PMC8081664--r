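Package: paralogon
Title: Synteny-Based Orthology and Duplication-Scenario Parsimony for Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-synteny toolkit for resolving orthology and paralogy of
    gene families across genomes, built around the oxytocin-vasotocin (OT/VT)
    ligand and receptor family in vertebrates. Provides gene-order containers
    with GFF3/BED readers, homology-hit filtering and family clustering,
    ten-gene microsynteny window profiles and orthogroup assignment,
    chromosome-scale collinear-chain detection with a top-two chi-squared test
    and gene-density normalization, intraspecies territory (paralogon)
    analysis, Dollo gain/loss reconstruction on a species tree, replayable
    genome-evolution scenarios with mutational step counting, gene-tree
    concordance checks, subfamily-diagnostic alignment sites, and a universal
    nomenclature renamer. Includes a synthetic genome-evolution simulator
    (tandem/segmental duplication, whole-genome duplication, loss, inversion,
    fission, translocation along a species tree) that emits genomes with known
    ground-truth orthology so every stage is testable without downloading
    genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    GenomicRanges,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
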