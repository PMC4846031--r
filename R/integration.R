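#' Combine EMR-concordant pairs with genetic overlap into three categories
#'
#' A pair significant in both EMRs and in the variant database is
#' "clinical_and_genetic"; significant in both EMRs only,
#' "clinical_without_genetic"; significant in the variant database but not
#' in both EMRs, "genetic_without_clinical".  Pairs with neither flag are
#' not assigned.  The genetic-only category is restricted to pairs whose
#' diseases share an age-incidence cluster (the same restriction the EMR
#' testing applies, so the absence of a clinical signal is meaningful) and
#' records which single EMR, if any, was significant.
#'
#' @param concordant From [concordant_pairs()]: pairs significant in both
#'   EMRs with a shared direction.
#' @param overlaps From [all_pairs_overlap()] (needs `significant`).
#' @param labels Named cluster labels for the diseases.
#' @param results_1,results_2 Optional per-source results from
#'   [test_within_clusters()], used to flag single-EMR significance for
#'   genetic-only pairs.
#' @param restrict_to_shared_diseases When `TRUE` (default), only pairs
#'   whose two diseases appear in the EMR results, the variant table, and
#'   the labels are considered.
#' @return data.frame of class `category_assignment`: pair, flags,
#'   `category`, `direction` (EMR pairs only), `single_source_flag`
#'   (genetic-only pairs significant in exactly one EMR), `cluster`.
#' @export
categorize <- function(concordant, overlaps, labels,
                       results_1 = NULL, results_2 = NULL,
                       restrict_to_shared_diseases = TRUE) {
  sig_ov <- overlaps[overlaps$significant, , drop = FALSE]
  emr_key <- pair_id(concordant$disease1, concordant$disease2)
  gen_key <- pair_id(sig_ov$disease1, sig_ov$disease2)
  shared_vocab <- if (restrict_to_shared_diseases) {
    emr_dis <- unique(c(concordant$disease1, concordant$disease2,
                        if (!is.null(results_1))
                          c(results_1$disease1, results_1$disease2),
                        if (!is.null(results_2))
                          c(results_2$disease1, results_2$disease2)))
    var_dis <- unique(c(overlaps$disease1, overlaps$disease2))
    intersect(intersect(emr_dis, var_dis), names(labels))
  } else NULL
  single_source <- function(d1, d2) {
    flag <- character(0)
    for (res in list(results_1, results_2)) {
      if (is.null(res)) next
      hit <- pair_id(res$disease1, res$disease2) == pair_id(d1, d2)
      if (any(hit & res$significant))
        flag <- c(flag, res$source_label[which(hit & res$significant)[1]])
    }
    if (length(flag) == 1) flag else NA_character_
  }
  all_keys <- union(emr_key, gen_key)
  rows <- lapply(all_keys, function(key) {
    parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    d1 <- parts[1]; d2 <- parts[2]
    if (!all(c(d1, d2) %in% names(labels)))
      stop("pair references disease(s) without a cluster label: ",
           paste(setdiff(c(d1, d2), names(labels)), collapse = ", "))
    if (!is.null(shared_vocab) && !all(c(d1, d2) %in% shared_vocab))
      return(NULL)
    emr_sig <- key %in% emr_key
    gen_sig <- key %in% gen_key
    same_cluster <- labels[[d1]] == labels[[d2]]
    category <- if (emr_sig && gen_sig) "clinical_and_genetic"
                else if (emr_sig) "clinical_without_genetic"
                else "genetic_without_clinical"
    if (category == "genetic_without_clinical" && !same_cluster)
      return(NULL)
    data.frame(
      disease1 = d1, disease2 = d2,
      emr_significant = emr_sig, genetic_significant = gen_sig,
      category = category,
      direction = if (emr_sig)
        concordant$direction[match(key, emr_key)] else NA_character_,
      single_source_flag = if (category == "genetic_without_clinical")
        single_source(d1, d2) else NA_character_,
      cluster = as.character(labels[[d1]]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(disease1 = character(), disease2 = character(),
                      emr_significant = logical(),
                      genetic_significant = logical(),
                      category = character(), direction = character(),
                      single_source_flag = character(),
                      cluster = character(), stringsAsFactors = FALSE)
  out <- out[order(out$disease1, out$disease2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' Export the concordant-pair network
#'
#' Builds the disease network (nodes: diseases with their frequency in a
#' reference source and cluster id; edges: concordant significant pairs
#' weighted by the reference source's observed/expected ratio) and writes it
#' as GraphML plus a plain tab-separated edge list.
#'
#' @param concordant From [concordant_pairs()].
#' @param reference_counts Named per-disease patient counts from the
#'   reference (typically larger) source, used for node size.
#' @param labels Named cluster labels.
#' @param graphml_path,edgelist_path Output paths (either may be `NULL` to
#'   skip writing).
#' @return The `igraph` graph, invisibly.
#' @export
export_network <- function(concordant, reference_counts, labels,
                           graphml_path = NULL, edgelist_path = NULL) {
  nodes <- sort(unique(c(names(reference_counts),
                         concordant$disease1, concordant$disease2)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            frequency = as.numeric(
                              ifelse(nodes %in% names(reference_counts),
                                     reference_counts[nodes], 0)),
                            cluster = as.character(
                              ifelse(nodes %in% names(labels),
                                     labels[nodes], NA)))
  if (nrow(concordant)) {
    edges <- rbind(concordant$disease1, concordant$disease2)
    g <- igraph::add_edges(g, as.vector(edges),
                           ratio = concordant$ratio_1,
                           direction = concordant$direction)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- data.frame(disease1 = concordant$disease1,
                     disease2 = concordant$disease2,
                     ratio = concordant$ratio_1,
                     direction = concordant$direction,
                     stringsAsFactors = FALSE)
    utils::write.table(el, edgelist_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(g)
}

#' Format a p-value in 2-decimal-mantissa scientific notation
#'
#' @param p Numeric p-values.
#' @return Character like `"6.22E-10"` (`"0.00E+00"` for underflow to 0).
#' @export
format_sci_p <- function(p) toupper(sprintf("%.2e", p))

#' Render the published-style report tables
#'
#' Produces the three report tables: overrepresented and underrepresented
#' EMR-significant pairs (with per-source Obs/Exp and p-value), and
#' genetic-only pairs (with set sizes, overlap, p, odds ratio, and the
#' single-EMR flag).  Rows are sorted by cluster, then by disease names, a
#' deterministic order.  P-values are printed in 2-decimal scientific
#' notation.
#'
#' @param assignments From [categorize()].
#' @param concordant From [concordant_pairs()].
#' @param overlaps From [all_pairs_overlap()].
#' @param out_dir Optional directory; when given, the tables are written as
#'   `emr_overrepresented.csv`, `emr_underrepresented.csv`,
#'   `genetic_only.csv`.
#' @return Named list of the three data.frames, invisibly when writing.
#' @export
render_report_tables <- function(assignments, concordant, overlaps,
                                 out_dir = NULL) {
  emr_rows <- assignments[assignments$emr_significant, , drop = FALSE]
  key_c <- pair_id(concordant$disease1, concordant$disease2)
  key_o <- pair_id(overlaps$disease1, overlaps$disease2)
  emr_table <- function(dir) {
    sub <- emr_rows[!is.na(emr_rows$direction) & emr_rows$direction == dir, ,
                    drop = FALSE]
    i <- match(pair_id(sub$disease1, sub$disease2), key_c)
    out <- data.frame(disease1 = sub$disease1, disease2 = sub$disease2,
                      cluster = sub$cluster,
                      obs_exp_1 = round(concordant$ratio_1[i], 2),
                      p_value_1 = format_sci_p(concordant$p_value_1[i]),
                      obs_exp_2 = round(concordant$ratio_2[i], 2),
                      p_value_2 = format_sci_p(concordant$p_value_2[i]),
                      category = sub$category, stringsAsFactors = FALSE)
    out[order(out$cluster, out$disease1, out$disease2), , drop = FALSE]
  }
  gen_rows <- assignments[assignments$category == "genetic_without_clinical", ,
                          drop = FALSE]
  i <- match(pair_id(gen_rows$disease1, gen_rows$disease2), key_o)
  genetic_only <- data.frame(
    disease1 = gen_rows$disease1, disease2 = gen_rows$disease2,
    cluster = gen_rows$cluster,
    size_1 = overlaps$size_1[i], size_2 = overlaps$size_2[i],
    overlap = overlaps$overlap[i],
    p_value = format_sci_p(overlaps$p_value[i]),
    odds_ratio = round(overlaps$odds_ratio[i], 2),
    emr = ifelse(is.na(gen_rows$single_source_flag), "",
                 gen_rows$single_source_flag),
    stringsAsFactors = FALSE)
  genetic_only <- genetic_only[order(genetic_only$disease1,
                                     genetic_only$disease2), , drop = FALSE]
  tables <- list(emr_overrepresented = emr_table("over"),
                 emr_underrepresented = emr_table("under"),
                 genetic_only = genetic_only)
  tables <- lapply(tables, function(x) { rownames(x) <- NULL; x })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    return(invisible(tables))
  }
  tables
}
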