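#' Canonical gene-group string
#'
#' A single variant can map to more than one gene; such genes form one
#' overlap unit, written as the unique symbols sorted alphabetically and
#' joined with colons (e.g. `"CAST:ERAP1"`).
#'
#' @param genes Nonempty character vector of gene symbols.
#' @return The canonical colon-joined group string.
#' @export
canonicalize_group <- function(genes) {
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (!length(genes)) stop("a gene group must contain at least one symbol")
  paste(sort(unique(unlist(strsplit(genes, ":", fixed = TRUE)))),
        collapse = ":")
}

#' Read a disease-gene variant-association table
#'
#' Expects a comma-separated file with at least `disease` and `gene`
#' columns; optional columns `snp`, `p_value`, `chromosome`, `pubmed_id`
#' are carried through.  When a `p_value` column is present, associations
#' with p at or above the threshold are dropped (strict `p < threshold`,
#' the conventional genome-wide cut for retaining an association); when the
#' table is pre-filtered and carries no p column, filtering is disabled.
#' Gene groups are canonicalized.
#'
#' @param path CSV file path.
#' @param p_threshold Association p-value cutoff (default `1e-6`); ignored
#'   when the file has no `p_value` column, set `NULL` to disable.
#' @return data.frame with canonical `gene` groups.
#' @export
read_variant_table <- function(path, p_threshold = 1e-6) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  missing_cols <- setdiff(c("disease", "gene"), names(raw))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[nzchar(raw$gene) & nzchar(raw$disease), , drop = FALSE]
  if ("p_value" %in% names(raw) && !is.null(p_threshold)) {
    p <- suppressWarnings(as.numeric(raw$p_value))
    raw <- raw[!is.na(p) & p < p_threshold, , drop = FALSE]
  }
  raw$gene <- vapply(raw$gene, canonicalize_group, "")
  rownames(raw) <- NULL
  raw
}

#' Build per-disease gene-group sets
#'
#' @param associations data.frame from [read_variant_table()] (gene groups
#'   already canonical).
#' @return Named list of class `gene_sets`: disease -> sorted character
#'   vector of distinct gene-group units.
#' @export
build_gene_sets <- function(associations) {
  sets <- lapply(split(associations$gene, associations$disease),
                 function(g) sort(unique(g)))
  structure(sets, class = "gene_sets")
}

#' Test the gene-set overlap of one disease pair for enrichment
#'
#' The 2x2 table partitions the gene universe into shared units, units
#' exclusive to either disease, and units in neither set; enrichment is the
#' Fisher exact test on that table (one-sided upper tail by default, since
#' the question is whether the overlap is *larger* than chance).  The odds
#' ratio is `(shared * neither) / (only1 * only2)`, 0 when the overlap is
#' empty and flagged infinite when an exclusive cell is empty.
#'
#' @param sets A `gene_sets` list.
#' @param disease1,disease2 Names of the two diseases in `sets`.
#' @param universe_size Size of the gene universe; must be at least the size
#'   of the union of the two sets.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return One-row data.frame: sizes, `overlap`, `p_value`, `odds_ratio`
#'   (with `or_infinite` flag), `universe_size`, and the shared unit names
#'   (comma-joined, sorted) in `shared_names`.
#' @export
overlap_test <- function(sets, disease1, disease2, universe_size,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  s1 <- sets[[disease1]]; s2 <- sets[[disease2]]
  if (is.null(s1) || is.null(s2))
    stop("unknown disease in gene sets: ",
         paste(setdiff(c(disease1, disease2), names(sets)), collapse = ", "))
  shared <- sort(intersect(s1, s2))
  n_shared <- length(shared)
  n_union <- length(union(s1, s2))
  if (universe_size < n_union)
    stop(sprintf("universe_size %d is smaller than the union (%d) for %s / %s",
                 universe_size, n_union, disease1, disease2))
  only1 <- length(s1) - n_shared
  only2 <- length(s2) - n_shared
  neither <- universe_size - n_union
  p <- fisher_exact_p(length(s1), length(s2), n_shared, universe_size,
                      alternative)
  or_inf <- n_shared > 0 && only1 * only2 == 0
  or <- if (n_shared == 0) 0
        else if (or_inf) Inf
        else (n_shared * neither) / (only1 * only2)
  data.frame(disease1 = disease1, disease2 = disease2,
             size_1 = length(s1), size_2 = length(s2),
             overlap = n_shared, p_value = p, odds_ratio = or,
             or_infinite = or_inf, universe_size = universe_size,
             shared_names = paste(shared, collapse = ", "),
             stringsAsFactors = FALSE)
}

#' Overlap-test all disease pairs with Bonferroni correction
#'
#' @param sets A `gene_sets` list (at least two diseases).
#' @param universe_size `"auto"` (default: the number of distinct gene-group
#'   units anywhere in `sets` — the database-relative universe) or an
#'   integer.
#' @param alpha Significance level (default 0.05); a pair is significant
#'   when `p < alpha / m` with `m` the number of tests performed.
#' @param restrict_pairs Optional data.frame `disease1`, `disease2` limiting
#'   which pairs are tested (m then equals the number of restricted pairs).
#' @param alternative Passed to [overlap_test()].
#' @return data.frame of all tested pairs (zero-overlap pairs included) with
#'   `significant` flags; attributes `m` and `universe_size`.
#' @export
all_pairs_overlap <- function(sets, universe_size = "auto", alpha = 0.05,
                              restrict_pairs = NULL,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(sets) >= 2)
  if (identical(universe_size, "auto"))
    universe_size <- length(unique(unlist(sets, use.names = FALSE)))
  if (is.null(restrict_pairs)) {
    cmb <- utils::combn(sort(names(sets)), 2)
    restrict_pairs <- data.frame(disease1 = cmb[1, ], disease2 = cmb[2, ],
                                 stringsAsFactors = FALSE)
  } else {
    restrict_pairs <- canonical_pair(restrict_pairs$disease1,
                                     restrict_pairs$disease2)
  }
  m <- nrow(restrict_pairs)
  rows <- lapply(seq_len(m), function(i)
    overlap_test(sets, restrict_pairs$disease1[i], restrict_pairs$disease2[i],
                 universe_size, alternative))
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha / m
  attr(out, "m") <- m
  attr(out, "universe_size") <- universe_size
  attr(out, "alpha") <- alpha
  out
}
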