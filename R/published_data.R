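#' Published disease counts and frequencies from two EMR systems
#'
#' The published summary table for the 35 diseases recorded in both EMR
#' systems (Columbia and Stanford) and in the variant-association database:
#' per-source patient counts with their printed frequencies (percent of the
#' roster), the per-disease gene count in the variant database, and the
#' hand-assigned life-stage name of the disease's age-incidence cluster.
#'
#' @return data.frame with columns `disease`, `columbia_count`,
#'   `columbia_percent`, `stanford_count`, `stanford_percent`, `n_genes`,
#'   `cluster_name`.
#' @seealso [published_roster_totals()], [published_pair_effects()]
#' @export
published_disease_counts <- function() {
  utils::read.csv(system.file("extdata", "published_disease_counts.csv",
                              package = "comorbinet"),
                  stringsAsFactors = FALSE)
}

#' Published roster totals for the two EMR systems
#'
#' The Columbia roster total of 1,478,976 includes healthy hospital
#' employees and is lowered by 500,000 before use; the Stanford total is the
#' 277,290 patients retained after the rollout-year and rare-disease
#' filters.
#'
#' @return Named numeric vector `c(columbia = 978976, stanford = 277290)`.
#' @export
published_roster_totals <- function() {
  c(columbia = 1478976 - 500000, stanford = 277290)
}

#' Published per-pair effect sizes and p-values
#'
#' The printed observed/expected ratios and Fisher p-values for the disease
#' pairs significant in both EMRs and in the variant database, plus the one
#' published protective pair (alcoholism/goiter).  Together with the
#' marginal counts of [published_disease_counts()] these determine the
#' observed both-disease count (`d = round(obs_exp * n1 * n2 / N)`), so the
#' full 2x2 test is reproducible from printed numbers alone.
#'
#' @return data.frame with columns `disease1`, `disease2`, `source`,
#'   `obs_exp`, `p_value` (printed 2-decimal scientific string),
#'   `direction`.
#' @export
published_pair_effects <- function() {
  utils::read.csv(system.file("extdata", "published_pair_effects.csv",
                              package = "comorbinet"),
                  stringsAsFactors = FALSE)
}

#' Reconstruct and retest a published disease pair
#'
#' Rebuilds the 2x2 table for one published pair in one source from the
#' printed marginals, roster total, and observed/expected ratio, then
#' recomputes the ratio and the two-sided Fisher p-value with this package's
#' engine.
#'
#' @param disease1,disease2 Disease names as printed.
#' @param source `"columbia"` or `"stanford"`.
#' @return One-row data.frame: the cells used and the recomputed `ratio`
#'   and `p_value`.
#' @export
retest_published_pair <- function(disease1, disease2, source) {
  counts <- published_disease_counts()
  eff <- published_pair_effects()
  totals <- published_roster_totals()
  row <- eff[eff$disease1 == disease1 & eff$disease2 == disease2 &
             eff$source == source, , drop = FALSE]
  if (nrow(row) != 1) stop("no published effect row for that pair/source")
  cc <- paste0(source, "_count")
  n1 <- counts[counts$disease == disease1, cc]
  n2 <- counts[counts$disease == disease2, cc]
  N <- totals[[source]]
  d <- round(row$obs_exp * n1 * n2 / N)
  tab <- build_table(n1, n2, d, N, pair = paste(disease1, disease2, sep = "/"))
  oe <- obs_exp_ratio(tab)
  data.frame(disease1 = disease1, disease2 = disease2, source = source,
             n1 = n1, n2 = n2, d = d, N = N,
             ratio = oe$ratio, p_value = fisher_exact_two_sided(tab),
             stringsAsFactors = FALSE)
}
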