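#!/usr/bin/env Rscript
# Combine the EMR-concordant pairs with the gene-overlap results into the
# three-way clinical/genetic classification, render the report tables, and
# export the disease network.

suppressPackageStartupMessages(library(comorbinet))

out_dir <- "results/integration"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cc <- read.csv("results/comorbidity/concordant_pairs.csv")
overlaps <- read.csv("results/genetic/overlap_results.csv")
r1 <- read.csv("results/comorbidity/source1_results.csv")
r2 <- read.csv("results/comorbidity/source2_results.csv")
lab_df <- read.csv("results/clusters/cluster_labels.csv")
labels <- setNames(lab_df$cluster, lab_df$disease)
dc1 <- read.csv("results/ingest/source1_disease_counts.csv")

assign <- categorize(cc, overlaps, labels, results_1 = r1, results_2 = r2)
message("category counts:")
print(table(assign$category))
write.csv(assign, file.path(out_dir, "category_assignments.csv"),
          row.names = FALSE)

render_report_tables(assign, cc, overlaps, out_dir = out_dir)
export_network(cc, setNames(dc1$count, dc1$disease), labels,
               graphml_path = file.path(out_dir, "network.graphml"),
               edgelist_path = file.path(out_dir, "network_edges.tsv"))
message("report tables and network written to ", out_dir)
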