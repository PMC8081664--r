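#!/usr/bin/env Rscript
# Chromosome-scale macrosynteny: collinear-chain gene hits from the lamprey
# chromosome carrying the OTR+VTR2B combination to every chromosome of the
# mammal genome, the chi-squared comparison of the two best chromosomes,
# gene-density normalization, and a 100-gene cumulative curve.

suppressPackageStartupMessages(library(paralogon))
dir.create("results", showWarnings = FALSE)

ds <- simulate_evolution(h1_receptor_config(), seed = 1)
lamprey <- ds$genomes$lampreys
mammal <- ds$genomes$mammals

ref_chrom <- lamprey$chrom[lamprey$gene_id == "VTR1_b"]   # carries OTR + VTR2B
ref <- as.data.frame(lamprey)[lamprey$chrom == ref_chrom, ]
counts <- chromosome_hit_counts(ref, mammal, min_pairs = 3, max_gap = 20)
write.table(data.frame(chrom = names(counts), hits = as.integer(counts)),
            "results/hit_counts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat("Reference:", ref_chrom, "(", nrow(ref), "genes ). Hits per mammal chromosome:\n")
print(counts)

t2 <- top2_test(counts, n_ref_genes = nrow(ref))
cat(sprintf("Top two: %s (%d) vs %s (%d); chi-squared = %.2f, df = 1, p = %.3g\n",
            t2$top[1], t2$counts_top[1], t2$top[2], t2$counts_top[2],
            t2$statistic, t2$p_value))
cat("The top chromosome is the WGD co-orthologue; the runner-up is its",
    "within-genome paralogon.\n")

totals <- table(mammal$chrom)
dn <- density_normalize(counts[counts > 0],
                        setNames(as.integer(totals), names(totals)))
cat(sprintf("Density normalization: top by count = %s, top by rate = %s (flag: %s)\n",
            dn$top_by_count, dn$top_by_rate, dn$flag))

cv <- cumulative_profile(lamprey, mammal, "VTR1_b", half_window = 25)
write.table(cv, "results/cumulative_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Cumulative 50-gene curve around lamprey OTR reaches",
    max(cv$cumulative), "hits.\n")
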