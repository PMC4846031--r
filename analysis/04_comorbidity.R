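#!/usr/bin/env Rscript
# Within-cluster comorbidity testing in both sources (two-sided Fisher
# exact, cell filter, per-cluster Bonferroni) and the concordance
# intersection across sources.

suppressPackageStartupMessages(library(comorbinet))

out_dir <- "results/comorbidity"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

lab_df <- read.csv("results/clusters/cluster_labels.csv")
labels <- setNames(lab_df$cluster, lab_df$disease)

results <- list()
for (src in c("source1", "source2")) {
  dc <- read.csv(sprintf("results/ingest/%s_disease_counts.csv", src))
  pcnt <- read.csv(sprintf("results/ingest/%s_pair_counts.csv", src))
  tab <- pair_count_table(100000, setNames(dc$count, dc$disease), pcnt, src)
  res <- test_within_clusters(tab, labels, alpha = 0.05,
                              bonferroni_mode = "diseases")
  message(sprintf("%s: %d same-cluster pairs tested, %d significant (%d over, %d under)",
                  src, nrow(res), sum(res$significant),
                  sum(res$significant & res$direction == "over"),
                  sum(res$significant & res$direction == "under")))
  write.csv(res, file.path(out_dir, paste0(src, "_results.csv")),
            row.names = FALSE)
  results[[src]] <- res
}

cc <- concordant_pairs(results$source1, results$source2)
message(sprintf("concordant in both sources: %d pair(s) (%d discordant excluded)",
                nrow(cc), nrow(attr(cc, "discordant"))))
print(cc[, c("disease1", "disease2", "direction", "ratio_1", "ratio_2")])
write.csv(cc, file.path(out_dir, "concordant_pairs.csv"), row.names = FALSE)
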