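#!/usr/bin/env Rscript
# Generate the gold synthetic dataset: three pseudo-species blocks with
# 14, 7 and 13 AMP precursor families, each a set of near-identical cDNAs
# with a known signal/propiece/mature segmentation.

library(ampevo)

cfg <- simulation_config(seed = 20200201)
g <- gold_dataset(cfg, "results/gold")

cat("families:", length(unique(g$truth$family)),
    "| records:", nrow(g$truth), "\n")
cat("species blocks:\n")
print(table(g$truth$species[!duplicated(g$truth$family)]))
cat("mature lengths:", min(g$truth$mature_len), "-", max(g$truth$mature_len),
    "residues\n")
cat("wrote", g$fasta, "/", g$metadata, "/", g$truth_file, "\n")
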