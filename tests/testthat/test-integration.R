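mk_concordant <- function(pairs, direction = "over") {
  if (!nrow(pairs))
    return(data.frame(disease1 = character(), disease2 = character(),
                      cluster = character(), direction = character(),
                      ratio_1 = numeric(), p_value_1 = numeric(),
                      ratio_2 = numeric(), p_value_2 = numeric(),
                      source_1 = character(), source_2 = character(),
                      stringsAsFactors = FALSE))
  data.frame(disease1 = pairs$disease1, disease2 = pairs$disease2,
             cluster = "c1", direction = direction,
             ratio_1 = 2, p_value_1 = 1e-8, ratio_2 = 2.5, p_value_2 = 1e-6,
             source_1 = "s1", source_2 = "s2", stringsAsFactors = FALSE)
}

mk_overlaps <- function(pairs, significant) {
  data.frame(disease1 = pairs$disease1, disease2 = pairs$disease2,
             size_1 = 30, size_2 = 40, overlap = ifelse(significant, 10, 0),
             p_value = ifelse(significant, 1e-9, 0.8),
             odds_ratio = ifelse(significant, 20, 0), or_infinite = FALSE,
             universe_size = 1000,
             shared_names = ifelse(significant, "G1, G2", ""),
             significant = significant, stringsAsFactors = FALSE)
}

labs4 <- c(A = "c1", B = "c1", C = "c1", D = "c1")

test_that("category assignment follows the significance truth table", {
  pairs <- data.frame(disease1 = c("A", "A", "B"),
                      disease2 = c("B", "C", "C"), stringsAsFactors = FALSE)
  conc <- mk_concordant(pairs[1:2, ])                  # A/B, A/C in both EMRs
  ov <- mk_overlaps(pairs, significant = c(TRUE, FALSE, TRUE))
  res <- categorize(conc, ov, labs4)
  get <- function(d1, d2) res$category[res$disease1 == d1 & res$disease2 == d2]
  expect_equal(get("A", "B"), "clinical_and_genetic")
  expect_equal(get("A", "C"), "clinical_without_genetic")
  expect_equal(get("B", "C"), "genetic_without_clinical")
  # every flagged pair gets exactly one category
  expect_equal(nrow(res), 3)
})

test_that("the truth table holds under random flag assignments", {
  set.seed(99)
  for (i in 1:200) {
    emr <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    gen <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    pairs <- data.frame(disease1 = c("A", "A", "B"),
                        disease2 = c("B", "C", "C"), stringsAsFactors = FALSE)
    res <- categorize(mk_concordant(pairs[emr, , drop = FALSE]),
                      mk_overlaps(pairs, gen), labs4,
                      restrict_to_shared_diseases = FALSE)
    lookup <- ifelse(emr & gen, "clinical_and_genetic",
              ifelse(emr, "clinical_without_genetic",
              ifelse(gen, "genetic_without_clinical", NA_character_)))
    expected <- data.frame(pairs, category = lookup,
                           stringsAsFactors = FALSE)
    expected <- expected[!is.na(expected$category), ]
    expect_equal(nrow(res), nrow(expected))
    key <- function(d) paste(d$disease1, d$disease2)
    expect_equal(res$category[match(key(expected), key(res))],
                 expected$category)
  }
})

test_that("genetic-only pairs require same-cluster membership and EMR flags", {
  pairs <- data.frame(disease1 = c("A", "A"), disease2 = c("B", "D"),
                      stringsAsFactors = FALSE)
  ov <- mk_overlaps(pairs, significant = c(TRUE, TRUE))
  labs <- c(A = "c1", B = "c1", C = "c1", D = "c2")
  r1 <- data.frame(disease1 = "A", disease2 = "B", cluster = "c1",
                   n1 = 1, n2 = 1, observed = 1, expected = 0.5, ratio = 2,
                   p_value = 1e-9, direction = "over", m = 3,
                   significant = TRUE, source_label = "columbia",
                   stringsAsFactors = FALSE)
  r2 <- r1; r2$significant <- FALSE; r2$source_label <- "stanford"
  res <- categorize(mk_concordant(pairs[0, ]), ov, labs,
                    results_1 = r1, results_2 = r2,
                    restrict_to_shared_diseases = FALSE)
  # A/D spans two clusters: not assigned at all
  expect_false(any(res$disease2 == "D"))
  ab <- res[res$disease1 == "A" & res$disease2 == "B", ]
  expect_equal(ab$category, "genetic_without_clinical")
  expect_equal(ab$single_source_flag, "columbia")
  # unknown disease in a pair is an error
  ov_bad <- mk_overlaps(data.frame(disease1 = "A", disease2 = "Z"), TRUE)
  expect_error(categorize(mk_concordant(pairs[0, ]), ov_bad, labs,
                          restrict_to_shared_diseases = FALSE),
               "without a cluster label")
})

test_that("network export produces the expected nodes, edges, and round-trip", {
  counts <- c(A = 100, B = 200, C = 50, D = 70, E = 10, F = 30)
  labs <- setNames(rep("c1", 6), names(counts))
  empty <- export_network(mk_concordant(data.frame(disease1 = character(),
                                                   disease2 = character())),
                          counts, labs)
  expect_equal(igraph::vcount(empty), 6)
  expect_equal(igraph::ecount(empty), 0)
  pairs <- data.frame(disease1 = c("A", "A", "B", "C", "E"),
                      disease2 = c("B", "C", "D", "F", "F"),
                      stringsAsFactors = FALSE)
  gpath <- tempfile(fileext = ".graphml")
  epath <- tempfile(fileext = ".tsv")
  g <- export_network(mk_concordant(pairs), counts, labs, gpath, epath)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 5)
  expect_equal(igraph::V(g)$frequency[match("B", igraph::V(g)$name)], 200)
  # GraphML round-trip preserves node and edge attribute multisets
  g2 <- igraph::read_graph(gpath, format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::V(g2)$frequency), sort(igraph::V(g)$frequency))
  expect_equal(sort(igraph::E(g2)$ratio), sort(igraph::E(g)$ratio))
  el <- utils::read.delim(epath)
  expect_equal(nrow(el), 5)
})

test_that("report tables are formatted and sorted deterministically", {
  expect_equal(format_sci_p(6.216e-10), "6.22E-10")
  expect_equal(format_sci_p(0), "0.00E+00")
  pairs <- data.frame(disease1 = c("B", "A"), disease2 = c("C", "B"),
                      stringsAsFactors = FALSE)
  conc <- mk_concordant(pairs)
  conc$ratio_1 <- c(46.88, 7.13)
  ov <- mk_overlaps(pairs, significant = c(FALSE, TRUE))
  asg <- categorize(conc, ov, labs4)
  tabs <- render_report_tables(asg, conc, ov)
  # sorted by cluster then disease names, not by effect size
  expect_equal(tabs$emr_overrepresented$disease1, c("A", "B"))
  expect_equal(tabs$emr_overrepresented$p_value_1, rep("1.00E-08", 2))
  expect_equal(nrow(tabs$emr_underrepresented), 0)  # header-only category
  expect_named(tabs, c("emr_overrepresented", "emr_underrepresented",
                       "genetic_only"))
  out <- tempfile()
  render_report_tables(asg, conc, ov, out_dir = out)
  expect_true(file.exists(file.path(out, "emr_overrepresented.csv")))
  written <- utils::read.csv(file.path(out, "emr_underrepresented.csv"))
  expect_equal(nrow(written), 0)
})
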