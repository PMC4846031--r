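#!/usr/bin/env Rscript
# Ingest the encounter-level records of both sources: rollout-year cutoff,
# age censoring, earliest-onset reduction through the ICD9 catalog, disease
# and pair counting, and the rare-disease filter.

suppressPackageStartupMessages(library(comorbinet))

out_dir <- "results/ingest"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (src in c("source1", "source2")) {
  sdir <- file.path("results/sim", src)
  enc <- read_encounters(file.path(sdir, "encounters.csv"),
                         year_min = 2008, age_cap = 90)
  catalog <- read_catalog(file.path(sdir, "catalog.csv"))
  onsets <- earliest_onset(enc, catalog)
  res <- count_diseases_and_pairs(onsets, roster_total = 100000,
                                  source_label = src)
  counts <- filter_rare(res$counts, min_patients = 50)
  message(sprintf("%s: %d encounters -> %d (patient, disease) onsets; %d/%d diseases pass the 50-patient filter",
                  src, nrow(enc), nrow(onsets),
                  length(counts$disease_counts),
                  length(res$counts$disease_counts)))
  write.csv(data.frame(disease = names(counts$disease_counts),
                       count = unname(counts$disease_counts)),
            file.path(out_dir, paste0(src, "_disease_counts.csv")),
            row.names = FALSE)
  write.csv(counts$pair_counts,
            file.path(out_dir, paste0(src, "_pair_counts.csv")),
            row.names = FALSE)
  hist <- res$histograms[names(counts$disease_counts), , drop = FALSE]
  write.csv(data.frame(disease = rownames(hist), hist, check.names = FALSE),
            file.path(out_dir, paste0(src, "_onset_histograms.csv")),
            row.names = FALSE)
}
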