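#' Build a 2x2 presence/absence contingency table for a disease pair
#'
#' Cell layout follows the conventional comorbidity table: `a` = neither
#' disease, `b` = disease 2 only, `c` = disease 1 only, `d` = both.
#'
#' @param n1,n2 Patient counts for disease 1 and disease 2.
#' @param d Count of patients with both.
#' @param N Roster total.
#' @param pair Optional pair label used in error messages.
#' @return Object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n1`, `n2`, `N`.
#' @export
build_table <- function(n1, n2, d, N, pair = NULL) {
  lab <- if (is.null(pair)) "" else paste0(" for pair ", pair)
  if (d > min(n1, n2))
    stop("both-disease count d exceeds a marginal count", lab)
  if (n1 + n2 - d > N)
    stop("n1 + n2 - d exceeds roster total N", lab)
  # store as doubles: cell products in downstream filters would overflow
  # 32-bit integers at roster sizes around 10^6
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  d <- as.numeric(d); N <- as.numeric(N)
  structure(list(a = N - n1 - n2 + d, b = n2 - d, c = n1 - d, d = d,
                 n1 = n1, n2 = n2, N = N),
            class = "contingency_table")
}

#' Minimum-cell filter for a 2x2 table
#'
#' A disease pair is excluded from testing when any of the four observed
#' cells, or any of the four expected cells under independence
#' (row total x column total / N), falls below `threshold`.  Small cells
#' make the independence test unstable and the published convention is to
#' drop such pairs.
#'
#' @param table A `contingency_table`.
#' @param threshold Minimum cell value (default 5).
#' @return `TRUE` if the pair passes, `FALSE` if it should be removed.
#' @export
cell_filter <- function(table, threshold = 5) {
  stopifnot(inherits(table, "contingency_table"))
  obs <- c(table$a, table$b, table$c, table$d)
  r1 <- table$a + table$b; r2 <- table$c + table$d
  c1 <- table$a + table$c; c2 <- table$b + table$d
  expd <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / table$N
  all(obs >= threshold) && all(expd >= threshold)
}

#' Observed and expected co-occurrence and their ratio
#'
#' Under independence the expected both-disease count is `n1 * n2 / N`; the
#' observed/expected ratio is the effect size reported for comorbid pairs
#' (ratio > 1: overrepresented/synergistic; < 1: underrepresented/protective).
#'
#' @param table A `contingency_table`.
#' @return list with `observed`, `expected`, `ratio` (`NaN`, flagged via the
#'   `undefined` field, when `expected` is 0).
#' @export
obs_exp_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$N == 0) stop("roster total N is zero")
  expected <- table$n1 * table$n2 / table$N
  list(observed = table$d, expected = expected,
       ratio = if (expected > 0) table$d / expected else NaN,
       undefined = expected == 0)
}

#' Test all same-cluster disease pairs in one EMR source
#'
#' Every unordered pair of diseases assigned to the same age-incidence
#' cluster is tested with the two-sided Fisher exact test; pairs whose
#' members fall in different clusters are never compared (the age-confounding
#' control).  Pairs failing [cell_filter()] are removed.  Significance is
#' raw p below `alpha / m` with `m` determined per cluster by
#' `bonferroni_mode`: `"diseases"` (the number of diseases in the cluster,
#' the published convention) or `"pairs"` (`k(k-1)/2`).  `m` counts cluster
#' membership, not the pairs surviving the cell filter.
#'
#' @param table A [pair_count_table()].
#' @param labels Named vector mapping disease to cluster id; diseases in
#'   `table` without a label are skipped with a warning.
#' @param alpha Significance level before correction (default 0.05).
#' @param bonferroni_mode `"diseases"` (default) or `"pairs"`.
#' @param cell_threshold Minimum observed/expected cell value (default 5);
#'   set to 0 to disable.
#' @return data.frame of class `comorbidity_result` with one row per tested
#'   pair: cells, expected count, ratio, p-value, direction (`"over"` iff
#'   observed > expected else `"under"`), significance, and the `m` used.
#'   Attribute `bonferroni_mode` records the convention.
#' @export
test_within_clusters <- function(table, labels, alpha = 0.05,
                                 bonferroni_mode = c("diseases", "pairs"),
                                 cell_threshold = 5) {
  stopifnot(inherits(table, "pair_count_table"))
  bonferroni_mode <- match.arg(bonferroni_mode)
  diseases <- names(table$disease_counts)
  unlabeled <- setdiff(diseases, names(labels))
  if (length(unlabeled)) {
    warning("skipping disease(s) without a cluster label: ",
            paste(unlabeled, collapse = ", "))
    diseases <- setdiff(diseases, unlabeled)
  }
  rows <- list()
  for (cl in unique(labels[diseases])) {
    members <- sort(diseases[labels[diseases] == cl])
    k <- length(members)
    if (k < 2) next
    m <- if (bonferroni_mode == "diseases") k else k * (k - 1) / 2
    cmb <- utils::combn(members, 2)
    for (j in seq_len(ncol(cmb))) {
      d1 <- cmb[1, j]; d2 <- cmb[2, j]
      n1 <- table$disease_counts[[d1]]; n2 <- table$disease_counts[[d2]]
      dd <- pair_count(table, d1, d2)
      tab <- build_table(n1, n2, dd, table$total_patients,
                         pair = paste(d1, d2, sep = " / "))
      if (cell_threshold > 0 && !cell_filter(tab, cell_threshold)) next
      oe <- obs_exp_ratio(tab)
      p <- fisher_exact_two_sided(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        disease1 = d1, disease2 = d2, cluster = cl,
        n1 = n1, n2 = n2, observed = dd,
        expected = oe$expected, ratio = oe$ratio, p_value = p,
        direction = if (dd > oe$expected) "over" else "under",
        m = m, significant = p < alpha / m,
        source_label = table$source_label,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease1 = character(), disease2 = character(),
               cluster = character(), n1 = integer(), n2 = integer(),
               observed = integer(), expected = numeric(), ratio = numeric(),
               p_value = numeric(), direction = character(), m = numeric(),
               significant = logical(), source_label = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "bonferroni_mode") <- bonferroni_mode
  attr(out, "alpha") <- alpha
  class(out) <- c("comorbidity_result", "data.frame")
  out
}

#' Intersect significant pairs across two EMR sources
#'
#' Keeps pairs that are significant in both sources with the same direction
#' of effect (both overrepresented or both underrepresented).  Discordant
#' pairs — significant in both but with opposite directions — are excluded
#' and returned in the `discordant` attribute.
#'
#' @param results_1,results_2 Results from [test_within_clusters()] on two
#'   independent sources.
#' @return data.frame with one row per concordant pair: the pair, cluster,
#'   shared direction, and per-source ratio and p-value (suffixes `_1`/`_2`).
#' @export
concordant_pairs <- function(results_1, results_2) {
  s1 <- results_1[results_1$significant, , drop = FALSE]
  s2 <- results_2[results_2$significant, , drop = FALSE]
  key1 <- pair_id(s1$disease1, s1$disease2)
  key2 <- pair_id(s2$disease1, s2$disease2)
  common <- intersect(key1, key2)
  i1 <- match(common, key1); i2 <- match(common, key2)
  same_dir <- s1$direction[i1] == s2$direction[i2]
  out <- data.frame(
    disease1 = s1$disease1[i1][same_dir],
    disease2 = s1$disease2[i1][same_dir],
    cluster = s1$cluster[i1][same_dir],
    direction = s1$direction[i1][same_dir],
    ratio_1 = s1$ratio[i1][same_dir], p_value_1 = s1$p_value[i1][same_dir],
    ratio_2 = s2$ratio[i2][same_dir], p_value_2 = s2$p_value[i2][same_dir],
    source_1 = if (nrow(s1)) s1$source_label[i1][same_dir] else character(),
    source_2 = if (nrow(s2)) s2$source_label[i2][same_dir] else character(),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  discordant <- data.frame(disease1 = s1$disease1[i1][!same_dir],
                           disease2 = s1$disease2[i1][!same_dir],
                           direction_1 = s1$direction[i1][!same_dir],
                           direction_2 = s2$direction[i2][!same_dir],
                           stringsAsFactors = FALSE)
  attr(out, "discordant") <- discordant
  out
}
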