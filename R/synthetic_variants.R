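#' Synthetic variant-association table configuration
#'
#' @param universe_size Total count of distinct gene symbols available.
#' @param genes_per_disease Named positive integer vector: disease -> number
#'   of distinct gene(-group) units associated with it.
#' @param planted_overlaps Optional data.frame `disease_a`, `disease_b`,
#'   `overlap`: the exact number of shared units for that unordered pair.
#'   Pairs not listed share nothing.
#' @param seed Integer seed.
#' @return Object of class `sim_variant_config`.
#' @export
sim_variant_config <- function(universe_size, genes_per_disease,
                               planted_overlaps = NULL, seed = 1) {
  stopifnot(universe_size > 0, !is.null(names(genes_per_disease)),
            all(genes_per_disease > 0))
  if (is.null(planted_overlaps))
    planted_overlaps <- data.frame(disease_a = character(),
                                   disease_b = character(),
                                   overlap = integer(),
                                   stringsAsFactors = FALSE)
  stopifnot(all(c("disease_a", "disease_b", "overlap") %in%
                names(planted_overlaps)))
  if (any(planted_overlaps$overlap < 0)) stop("overlaps must be nonnegative")
  unknown <- setdiff(c(planted_overlaps$disease_a, planted_overlaps$disease_b),
                     names(genes_per_disease))
  if (length(unknown))
    stop("planted overlaps reference undeclared disease(s): ",
         paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(planted_overlaps))) {
    a <- planted_overlaps$disease_a[i]; b <- planted_overlaps$disease_b[i]
    if (planted_overlaps$overlap[i] >
        min(genes_per_disease[[a]], genes_per_disease[[b]]))
      stop(sprintf("planted overlap for %s / %s exceeds the smaller set size",
                   a, b))
  }
  # per-disease: genes committed to shared blocks cannot exceed the set size
  shared_per_disease <- tapply(
    c(planted_overlaps$overlap, planted_overlaps$overlap),
    c(planted_overlaps$disease_a, planted_overlaps$disease_b), sum)
  over <- names(shared_per_disease)[
    shared_per_disease > genes_per_disease[names(shared_per_disease)]]
  if (length(over))
    stop("pairwise overlap constraints unsatisfiable for disease(s): ",
         paste(over, collapse = ", "),
         " (sum of planted overlaps exceeds the set size)")
  need <- sum(genes_per_disease) - sum(planted_overlaps$overlap)
  if (need > universe_size)
    stop(sprintf("universe_size %d too small: %d distinct genes required",
                 universe_size, need))
  structure(list(universe_size = as.integer(universe_size),
                 genes_per_disease = genes_per_disease,
                 planted_overlaps = planted_overlaps,
                 seed = as.integer(seed)),
            class = "sim_variant_config")
}

#' Simulate a variant-association table with exact planted overlaps
#'
#' Each planted pair is assigned a dedicated block of shared gene symbols;
#' the remainder of every disease's set is filled with symbols used by no
#' other disease.  Pairwise shared counts therefore equal the planted
#' overlaps exactly and per-disease distinct gene counts equal
#' `genes_per_disease` exactly, by construction.
#'
#' @param config A [sim_variant_config()].
#' @return data.frame with columns `disease`, `gene`, `chromosome`,
#'   `pubmed_id` (one row per disease-gene association), deterministic under
#'   the config seed.
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "sim_variant_config"))
  with_seed(config$seed, {
    sizes <- config$genes_per_disease
    universe <- sprintf("G%05d", sample.int(config$universe_size))
    sets <- lapply(sizes, function(...) character())
    cursor <- 0L
    take <- function(k) {
      out <- universe[cursor + seq_len(k)]
      cursor <<- cursor + k
      out
    }
    po <- config$planted_overlaps
    for (i in seq_len(nrow(po))) {
      block <- take(po$overlap[i])
      sets[[po$disease_a[i]]] <- c(sets[[po$disease_a[i]]], block)
      sets[[po$disease_b[i]]] <- c(sets[[po$disease_b[i]]], block)
    }
    for (dn in names(sizes))
      sets[[dn]] <- c(sets[[dn]], take(sizes[[dn]] - length(sets[[dn]])))
    rows <- data.frame(
      disease = rep(names(sets), lengths(sets)),
      gene = unlist(sets, use.names = FALSE),
      stringsAsFactors = FALSE)
    rows$chromosome <- as.character(sample(1:22, nrow(rows), replace = TRUE))
    rows$pubmed_id <- sprintf("%08d", sample.int(99999999L, nrow(rows),
                                                 replace = TRUE))
    rows <- rows[order(rows$disease, rows$gene), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
}
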