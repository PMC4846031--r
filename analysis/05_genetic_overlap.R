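#!/usr/bin/env Rscript
# Gene-set overlap enrichment between all disease pairs in the variant
# table: per-disease gene-group sets, one-sided Fisher overlap tests with
# Bonferroni correction over the number of pairs.

suppressPackageStartupMessages(library(comorbinet))

out_dir <- "results/genetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

assoc <- read_variant_table("results/sim/variants.csv")
sets <- build_gene_sets(assoc)
message(sprintf("%d diseases with gene sets (sizes %d-%d)",
                length(sets), min(lengths(sets)), max(lengths(sets))))

overlaps <- all_pairs_overlap(sets, universe_size = 17000, alpha = 0.05)
sig <- overlaps[overlaps$significant, ]
message(sprintf("%d of %d pairs significant after Bonferroni (m = %d)",
                nrow(sig), nrow(overlaps), attr(overlaps, "m")))
print(sig[, c("disease1", "disease2", "size_1", "size_2", "overlap")])
write.csv(overlaps, file.path(out_dir, "overlap_results.csv"),
          row.names = FALSE)
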