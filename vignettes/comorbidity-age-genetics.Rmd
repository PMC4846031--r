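---
title: "Age-aware disease comorbidity testing with genetic-overlap integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-aware disease comorbidity testing with genetic-overlap integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbinet)
```

## The problem

Two diseases that occur in the same patients more often than chance predicts
(synergistic comorbidity) or less often (protective, or inverse,
comorbidity) point at shared mechanism: common genetic architecture, shared
exposures, or one disease modifying the risk of the other.  Electronic
medical records (EMRs) are large enough to screen all pairs of a disease
catalog systematically, but they carry a specific confounder: an EMR covers
a limited window of calendar time, so two diseases whose onsets fall at
distant ages (say, a childhood-onset and an old-age-onset disorder) are
systematically undercounted as a pair even if they are biologically linked —
the same person is rarely observed in both life stages.  Left uncorrected,
this manufactures spurious "protective" pairs.

This package implements a screening pipeline that addresses that confounder
by *clustering diseases on the shape of their age-at-onset distribution* and
testing pairs only within a cluster, then validates signals across two
independent record systems, and finally asks whether each surviving pair is
also supported by overlap of its disease-associated gene sets in a variant
database.  Each pair ends up in one of three categories: *clinical and
genetic*, *clinical without observed genetic effect*, or *genetic without
observed clinical effect*.

## The statistical core

For a disease pair $(i, j)$ in one source, the unit of evidence is the
2×2 presence/absence table over the roster of $N$ patients with cells
$a$ (neither), $b$ ($j$ only), $c$ ($i$ only), $d$ (both).  Under
independence the expected value of $d$ is $n_i n_j / N$ with
$n_i = c + d$, $n_j = b + d$; the effect size reported is the ratio
$d / (n_i n_j / N)$, and significance is the two-sided Fisher exact test —
the sum of the probabilities of all tables with the observed margins that
are no more probable than the observed one.  Direction (over- vs
under-represented) is read off the comparison of $d$ to its expectation
after the single two-sided significance call, so both tails come from one
test.

The test is computed in log space from `lchoose` terms, which keeps it
stable at roster sizes of $10^6$ and p-values far below the double-precision
underflow of naive summation (underflowed sums print as `0.00E+00`, as such
values are conventionally reported).  A table is compared to the observed
one with a relative tolerance of $10^{-7}$ so the observed table is never
excluded from its own tail by floating-point error.

## Age-incidence clustering

Each disease is a 91-dimensional vector of earliest-onset counts at integer
ages 0–90, divided by its Euclidean length so only the *shape* of the
incidence curve matters.  Ward hierarchical clustering on Euclidean
distances produces the final partition; k-means and k-medoids labelings are
also computed because the number of clusters is selected from a composite
over methods:

1. every (method, k) labeling for k in a search range (default 2–10) is
   scored by a panel of internal validity indices — silhouette width,
   Calinski–Harabasz, Dunn, Davies–Bouldin (negated), connectivity
   (negated), and the gap statistic — all sign-aligned so larger is better;
2. any index that is a *strictly* monotone function of k for every method is
   removed, since it would always be optimized at an end of the search range
   (non-strict sequences are kept: a plateau still carries peak
   information);
3. each retained index is z-standardized across all its cells, the
   standardized scores are averaged per k, and the chosen k is a local
   maximum of the composite — greater than both neighbors, boundary values
   qualifying against their single neighbor, the highest maximum winning and
   ties broken toward smaller k.

A local (not global) optimum is deliberate: the composite often drifts
upward or downward over the whole range, and the interior peak is the
data-driven signal.  Standardization is computed jointly across the whole
(method, k) grid per measure; this is the simplest reading of "standardize
each measure" and makes the composite invariant to each index's affine
scale, which is the property that matters (the package's tests check
exactly that invariance).  Indices that cannot be computed for a labeling —
for example a degenerate single-cluster labeling — are marked failed and
excluded from the composite rather than silently dropped.

Pairs are then tested *only when both diseases carry the same cluster
label*.  This is conservative: genuinely linked pairs with different onset
profiles are not tested at all, which is the accepted cost of removing the
observation-window artifact.

## Multiplicity, filters, and concordance

Within each cluster, a pair is kept only if all four observed cells and all
four expected cells (row total × column total / N) are at least 5 (default);
smaller cells make the exact test uninformative and such pairs are
conventionally removed.  Significance is raw p below `alpha / m` with
`alpha = 0.05` and `m` the number of *diseases* in the cluster — the
published convention this pipeline follows — with `m = k(k-1)/2` (the number
of pairs, the statistically conventional count) available as
`bonferroni_mode = "pairs"`.  Both conventions are recorded in the result's
attributes; `m` counts cluster membership, not the pairs surviving the cell
filter.  Reported p-values are always raw.

A pair is accepted only when significant in *both* sources with the *same*
direction; discordant pairs (significant in both, opposite directions) are
excluded and logged.  Requiring concordant replication in two systems with
different populations and coding habits is the main guard against
source-specific ascertainment artifacts.

## Genetic overlap

The variant table maps diseases to *gene groups*: when one variant maps to
several genes, the symbols are sorted and colon-joined (`"CAST:ERAP1"`) and
that string is the overlap unit, so `"GLT8D1"` and `"GLT8D1:GNL3"` are
distinct units and printed shared-name lists reproduce verbatim.  When the
table carries association p-values, rows with $p \ge 10^{-6}$ are dropped
(strict inequality); pre-filtered tables without a p column are taken as
is.

For a disease pair the 2×2 table partitions a gene universe into shared /
exclusive-to-1 / exclusive-to-2 / neither, and enrichment is the one-sided
(upper-tail) Fisher exact test — "enrichment" is inherently one-sided; a
two-sided option exists.  The universe size defaults to the number of
distinct gene-group units present anywhere in the loaded table
(database-relative).  No external convention for this universe is
authoritative, odds ratios depend on it strongly, and back-solving published
odds ratios for an implied universe gives mutually inconsistent answers
across rows — so the universe actually used is always recorded in the
output, and odds ratios should be compared only within one universe
convention.  Bonferroni correction uses the number of overlap tests
performed.  Zero-overlap pairs are reported, not dropped; the integration
stage needs them.

## Integration

The three-way classification is a pure function of the two significance
flags: EMR-concordant and genetic-significant → *clinical and genetic*;
EMR-concordant only → *clinical without observed genetic effect*;
genetic-significant but not concordant in both EMRs → *genetic without
observed clinical effect*.  The genetic-only category additionally requires
the pair to share an age-incidence cluster (the same restriction the EMR
arm applies, so "no clinical signal" is a meaningful absence rather than an
untested comparison) and records which single EMR, if any, was significant.
Report tables are sorted by cluster and then by disease names — a
deterministic order chosen over effect-size sorting, whose published usage
is internally inconsistent — and the network export (GraphML plus a TSV
edge list) carries disease frequency and cluster id on nodes and the
observed/expected ratio on edges.

## The synthetic cohort generator

Because encounter-level EMRs and the variant database are protected, the
package ships a generator that emulates exactly the features the pipeline
is sensitive to, and nothing more:

- **age profiles**: each disease has a mixture of one or two Gaussian bumps
  over ages 0–90, discretized to 91 integer-age bins; life stages are
  emulated by bump placement (defaults in the analysis scripts: centers at
  5, 25, 50, 75 years, SD 5, prevalences 1–6%).
- **planted pairwise dependence**: a pair $(i,j)$ with multiplier $\rho$ has
  joint probability $\rho\,p_i p_j$ with marginals preserved; sampling is
  sequential-conditional (a disease already fixed by an earlier pair is
  conditioned on), all other pairs independent, and infeasible joints
  ($\rho p_i p_j > \min(p_i, p_j)$) are an error naming the pair.
- **two sources, one truth**: the two EMR sources are independent draws
  from the same configuration with different seeds, mirroring a
  discovery/validation design.
- **variant tables**: per-pair shared gene blocks are disjoint and filler
  genes are unique per disease, so set sizes and pairwise overlaps equal
  their planted values *exactly* (three-way-shared genes are never
  generated; pairwise targets are all the pipeline tests).

What the generator does **not** emulate: repeat-visit structure and
censoring by death, correlation between onset ages of comorbid diseases
(onset is drawn independently of co-disease status — the age correction
targets marginal incidence shape, not joint age structure), gender or
ethnicity structure, and miscoding.  Passing tests therefore demonstrate
correctness of the *method* under its own assumptions, not robustness to
every failure mode of real EMR data.

## Numerical and scale choices

Fisher tie tolerance $10^{-7}$ (relative); exhaustive-enumeration agreement
is verified to $10^{-10}$ for all ~324,000 tables with $N \le 60$.  The
test suite uses: 100 replicates of 20-disease null cohorts at n = 50,000
for the false-positive bound; 100 replicates of planted $\rho = 3$ and
$\rho = 0.3$ pairs (2% marginals, n = 100,000 per source) for recovery; 50
seeds of 40 diseases from 4 planted profiles (300 onsets per disease) for
cluster-count recovery; these sizes give stable rates while keeping the
default suite to a few minutes.  k-means uses 10 restarts; the gap
statistic uses 25 uniform reference draws over the feature ranges,
reclustered with the same method (k-means for externally supplied
labelings).  All generators take explicit seeds and restore the caller's
RNG state.

## Known limitations

- Cross-cluster disease pairs are never tested; that blind spot is by
  design.
- The within-cluster Bonferroni uses the disease count by default, which is
  *less* conservative than the pair count for clusters larger than 3;
  switch to `"pairs"` if strict family-wise control over pairs is wanted.
- Gene-overlap odds ratios are universe-relative and not comparable across
  universe conventions.
- Aggregate-count sources carry no onset histograms, so cluster labels must
  come from a patient-level source; the pipeline applies one source's
  clustering to both.
- The categorization treats "not significant" as "no effect"; absence from
  the variant database in particular reflects research attention as much as
  biology.
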