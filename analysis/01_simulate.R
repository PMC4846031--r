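#!/usr/bin/env Rscript
# Generate the synthetic study inputs: two independent EMR sources drawn
# from one shared ground truth (age-structured incidence, planted
# synergistic and protective pairs) and a variant-association table with
# planted gene-set overlaps.  Downstream steps consume only the files
# written here, mirroring an analysis that starts from exported data.

suppressPackageStartupMessages(library(comorbinet))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930

# Four life-stage incidence shapes (early childhood, young adult, midlife,
# old age), ten diseases each.  Prevalences 1-6%.
centers <- c(5, 25, 50, 75)
set.seed(seed)
profiles <- lapply(1:40, function(i)
  age_profile(sprintf("D%02d", i),
              centers = centers[(i - 1) %% 4 + 1] + runif(1, -2, 2),
              widths = 5, prevalence = runif(1, 0.01, 0.06)))

# Planted effects: one synergistic and one protective pair, both within the
# midlife group so they survive the same-cluster restriction.
planted <- data.frame(disease_a = c("D03", "D11"),
                      disease_b = c("D07", "D15"),
                      risk_multiplier = c(3, 0.3))

for (src in c("source1", "source2")) {
  cfg <- sim_config(100000, profiles, planted,
                    seed = seed + match(src, c("source1", "source2")))
  sim <- simulate_emr(cfg)
  write_sim_emr(sim, file.path(out_dir, src))
  message(sprintf("%s: %d encounter rows for %d patients", src,
                  nrow(sim$encounters), cfg$n_patients))
}

# Variant table: the synergistic pair also shares genes; the protective
# pair does not; one same-cluster pair with no EMR effect shares genes, so
# all three clinical/genetic categories appear downstream.
vcfg <- sim_variant_config(
  universe_size = 17000,
  genes_per_disease = setNames(sample(20:350, 40, replace = TRUE),
                               sprintf("D%02d", 1:40)),
  planted_overlaps = data.frame(disease_a = c("D03", "D19"),
                                disease_b = c("D07", "D23"),
                                overlap = c(12, 30)),
  seed = seed)
variants <- simulate_variants(vcfg)
write.csv(variants, file.path(out_dir, "variants.csv"), row.names = FALSE)
message(sprintf("variant table: %d associations over %d diseases",
                nrow(variants), length(unique(variants$disease))))
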