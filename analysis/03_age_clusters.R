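#!/usr/bin/env Rscript
# Age-incidence clustering on source 1's onset histograms: unit vectors,
# Ward/k-means/k-medoids over k = 2..10, composite of standardized validity
# measures after monotone-measure removal, locally optimal k, and the
# per-cluster mean incidence profiles.

suppressPackageStartupMessages(library(comorbinet))

out_dir <- "results/clusters"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

h_raw <- read.csv("results/ingest/source1_onset_histograms.csv",
                  check.names = FALSE)
hist <- as.matrix(h_raw[, -1])
rownames(hist) <- h_raw$disease
storage.mode(hist) <- "integer"

vectors <- build_vectors(hist)
labelings <- cluster_solutions(vectors, k_range = 2:10, seed = 1)
grid <- score_grid(labelings, vectors, seed = 1)
grid2 <- remove_monotonic(grid)
sel <- select_k(grid2, labelings)

message(sprintf("chosen k = %d; removed monotone measure(s): %s",
                sel$chosen_k,
                if (length(sel$removed_measures))
                  paste(sel$removed_measures, collapse = ", ") else "none"))
message("composite by k: ",
        paste(sprintf("%s=%.2f", names(sel$composite_by_k),
                      sel$composite_by_k), collapse = " "))

write.csv(as.data.frame(grid), file.path(out_dir, "validity_grid.csv"),
          row.names = FALSE)
write.csv(data.frame(k = names(sel$composite_by_k),
                     composite = unname(sel$composite_by_k)),
          file.path(out_dir, "composite_by_k.csv"), row.names = FALSE)
write.csv(data.frame(disease = names(sel$final_labels),
                     cluster = unname(sel$final_labels)),
          file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)
prof <- cluster_profiles(sel, hist)
write.csv(data.frame(cluster = rownames(prof), prof, check.names = FALSE),
          file.path(out_dir, "cluster_profiles.csv"), row.names = FALSE)
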