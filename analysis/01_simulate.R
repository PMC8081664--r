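#!/usr/bin/env Rscript
# Generate the synthetic vertebrate panel: the one-WGD + segmental-
# duplication receptor history played over ten lineages, with the OT/VT
# tandem duplication, lineage-specific losses, the mammalian fission and
# the teleost/holostean OT rearrangements. Writes one gene-order TSV per
# species plus the ground-truth locus status table.

suppressPackageStartupMessages(library(paralogon))
dir.create("results/genomes", showWarnings = FALSE, recursive = TRUE)

seed <- 1
cfg <- h1_receptor_config()
ds <- simulate_evolution(cfg, seed = seed)

for (sp in names(ds$genomes))
  write_genome_tsv(ds$genomes[[sp]], file.path("results/genomes", paste0(sp, ".tsv")))

truth <- truth_orthogroups(ds, cfg$receptor_family)
write.table(truth, "results/truth_status.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Simulated", length(ds$genomes), "genomes (seed", seed, ") with",
    length(ds$event_log), "events.\n")
rep_counts <- vapply(ds$genomes, function(g) sum(g$family == "VTR"), integer(1))
cat("Receptor genes per lineage:\n")
print(rep_counts)
cat("The hagfish genome carries",
    sum(ds$genomes$hagfishes$family == "VTR"),
    "receptor genes on two scaffolds - the ancestral VTR1/VTR2 state.\n")
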