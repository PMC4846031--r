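Package: comorbinet
Title: Disease Comorbidity Networks from Electronic Medical Records with
    Age-Incidence Clustering and Genetic Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects under- and over-represented disease pairs in
    encounter-level electronic medical records while controlling for the
    confounding effect of age on disease incidence.  Diseases are represented
    as unit-normalized 91-bin earliest-onset-age histograms and grouped by
    Ward hierarchical clustering; the number of clusters is chosen by a
    composite of standardized cluster-validity indices after removing indices
    that vary monotonically with cluster count.  Disease pairs are tested
    within clusters with a two-sided Fisher exact test and Bonferroni
    correction, and pairs concordantly significant in two independent record
    systems are intersected with gene-set overlap enrichment from a
    variant-association table to yield a three-way clinical/genetic
    classification.  Includes a seeded synthetic-cohort generator with
    planted pairwise risk multipliers and planted gene-set overlaps so the
    full pipeline is testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    data.table,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
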