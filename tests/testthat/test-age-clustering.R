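test_that("incidence vectors are unit normalized", {
  h <- matrix(0L, 2, 91, dimnames = list(c("a", "b"), as.character(0:90)))
  h["a", 1:2] <- c(3L, 4L)
  h["b", 50] <- 7L
  v <- build_vectors(h)
  expect_equal(v["a", 1:2], c("0" = 0.6, "1" = 0.8))
  expect_equal(unname(sqrt(rowSums(v^2))), c(1, 1), tolerance = 1e-9)
  h["b", ] <- 0L
  expect_error(build_vectors(h), "b")
})

test_that("all methods recover two well-separated groups at k = 2", {
  h <- planted_histograms(n_diseases = 12, seed = 2)
  # keep only two of the four planted groups
  keep <- attr(h, "truth") %in% c(1, 3)
  truth <- attr(h, "truth")[keep]
  v <- build_vectors(h[keep, , drop = FALSE])
  lab <- cluster_solutions(v, k_range = 2:3, seed = 1)
  for (m in names(lab)) {
    l2 <- lab[[m]][["2"]]
    expect_equal(length(unique(l2)), 2)
    # partition identical to the planted one up to relabeling
    expect_equal(length(unique(paste(l2, truth))), 2,
                 label = paste("method", m))
  }
})

test_that("k equal to the number of diseases gives singletons; beyond errors", {
  h <- planted_histograms(n_diseases = 6, seed = 3)
  v <- build_vectors(h)
  lab <- cluster_solutions(v, methods = "ward", k_range = 6)
  expect_equal(sort(unname(lab$ward[["6"]])), 1:6)
  expect_error(cluster_solutions(v, k_range = 2:7), "exceeds")
})

test_that("ward labels match planted ground truth on separated profiles", {
  h <- planted_histograms(n_diseases = 40, seed = 4)
  v <- build_vectors(h)
  lab <- cluster_solutions(v, methods = "ward", k_range = 4)
  cross <- table(lab$ward[["4"]], attr(h, "truth"))
  expect_true(all(rowSums(cross > 0) == 1))  # adjusted Rand = 1
})

test_that("the ward partition and chosen k are invariant to input order", {
  h <- planted_histograms(n_diseases = 24, seed = 5)
  run <- function(hh) {
    v <- build_vectors(hh)
    lab <- cluster_solutions(v, k_range = 2:6, seed = 1)
    sel <- select_k(remove_monotonic(score_grid(lab, v, seed = 1)), lab)
    sel
  }
  s1 <- run(h)
  perm <- sample(nrow(h))
  s2 <- run(h[perm, , drop = FALSE])
  expect_equal(s2$chosen_k, s1$chosen_k)
  l1 <- s1$final_labels[sort(names(s1$final_labels))]
  l2 <- s2$final_labels[sort(names(s2$final_labels))]
  expect_equal(length(unique(paste(l1, l2))), s1$chosen_k)  # same partition
})

test_that("validity scores are aligned, and degenerate labelings fail", {
  # two groups of identical vectors: perfect separation
  p1 <- age_profile("p1", 10, 5, prevalence = 0.01)$density
  p2 <- age_profile("p2", 70, 5, prevalence = 0.01)$density
  h <- round(rbind(p1, p1, p1, p2, p2, p2) * 1000)
  dimnames(h) <- list(sprintf("D%d", 1:6), as.character(0:90))
  v <- build_vectors(h)
  planted <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(v))
  labelings <- list(ward = list("2" = planted))
  grid <- score_grid(labelings, v, measures = c("silhouette", "dunn"))
  sil <- grid$score[grid$measure == "silhouette"]
  expect_equal(sil, 1)  # the maximum attainable value
  # cross-check the silhouette index against the reference implementation
  ref <- mean(cluster::silhouette(planted, stats::dist(v))[, 3])
  expect_equal(sil, ref, tolerance = 1e-12)
  # a single-cluster labeling is marked failed, not dropped
  one <- list(ward = list("1" = setNames(rep(1L, nrow(v)), rownames(v))))
  g1 <- score_grid(one, v, measures = c("silhouette", "calinski_harabasz",
                                        "dunn"))
  expect_true(all(g1$failed))
  expect_equal(nrow(g1), 3)
})

test_that("planted labels outscore random labels on every aligned measure", {
  h <- planted_histograms(n_diseases = 24, seed = 7)
  v <- build_vectors(h)
  planted <- setNames(attr(h, "truth"), rownames(v))
  set.seed(1)
  random <- setNames(sample(planted), rownames(v))
  labelings <- list(ward = list("4" = planted), shuffled = list("4" = random))
  grid <- score_grid(labelings, v, seed = 2)
  for (meas in unique(grid$measure)) {
    sp <- grid$score[grid$method == "ward" & grid$measure == meas]
    sr <- grid$score[grid$method == "shuffled" & grid$measure == meas]
    expect_gt(sp, sr, label = meas)
  }
})

test_that("strictly monotone measures are removed, peaked ones retained", {
  mk_grid <- function(scores) {
    # scores: named list measure -> k-indexed vector, replicated per method
    rows <- do.call(rbind, lapply(names(scores), function(meas)
      do.call(rbind, lapply(c("ward", "kmeans"), function(m)
        data.frame(method = m, k = 2:6, measure = meas,
                   score = scores[[meas]], failed = FALSE,
                   stringsAsFactors = FALSE)))))
    attr(rows, "k_range") <- 2:6
    class(rows) <- c("validity_grid", "data.frame")
    rows
  }
  grid <- mk_grid(list(
    inc = 2:6,                       # strictly increasing: removed
    dec = 6:2,                       # strictly decreasing: removed
    flat = rep(1, 5) + c(0, 0, 0, 0, 0),  # constant: retained (non-strict)
    peak = c(0, 2, 5, 1, 0),         # interior peak: retained
    plateau = c(0, 1, 1, 2, 3),      # plateau then rise: retained
    vee = c(3, 1, 0, 1, 3)))         # interior minimum: retained
  out <- remove_monotonic(grid)
  expect_setequal(attr(out, "removed_measures"), c("inc", "dec"))
  expect_setequal(unique(out$measure), c("flat", "peak", "plateau", "vee"))
  # a measure monotone for one method but peaked for another is retained
  grid2 <- mk_grid(list(peak = c(0, 2, 5, 1, 0)))
  grid2$score[grid2$method == "kmeans"] <- 2:6
  expect_equal(attr(remove_monotonic(grid2), "removed_measures"), character())
  # removing everything is an error
  expect_error(remove_monotonic(mk_grid(list(inc = 2:6))), "measure set")
})

test_that("the composite selects a local maximum with small-k tie-breaks", {
  mk <- function(comp, ks = 2:6) {
    grid <- data.frame(method = "ward", k = ks, measure = "m1",
                       score = comp, failed = FALSE, stringsAsFactors = FALSE)
    attr(grid, "k_range") <- ks
    class(grid) <- c("validity_grid", "data.frame")
    labelings <- list(ward = setNames(
      lapply(ks, function(k) setNames(rep_len(seq_len(k), 10),
                                      sprintf("D%02d", 1:10))),
      as.character(ks)))
    select_k(grid, labelings)
  }
  # interior peak (z-standardization preserves the shape)
  expect_equal(mk(c(-1.0, 0.2, 0.9, 0.4, 0.1))$chosen_k, 4)
  # two equal local maxima: the smaller k wins
  expect_equal(mk(c(0, 1, 0, 1, 0))$chosen_k, 3)
  # boundary local maximum qualifies
  expect_equal(mk(c(5, 4, 3, 2, 1))$chosen_k, 2)
  # flat composite is an error
  expect_error(mk(rep(1, 5)), "flat")
})

test_that("the composite is invariant to a measure's affine scale", {
  h <- planted_histograms(n_diseases = 20, seed = 8)
  v <- build_vectors(h)
  lab <- cluster_solutions(v, methods = c("ward", "kmeans"), k_range = 2:6,
                           seed = 1)
  grid <- score_grid(lab, v, measures = c("silhouette", "calinski_harabasz",
                                          "dunn"))
  g2 <- grid
  idx <- g2$measure == "calinski_harabasz"
  g2$score[idx] <- g2$score[idx] * 1000 + 5   # rescale one measure
  s1 <- select_k(grid, lab)
  s2 <- select_k(g2, lab)
  expect_equal(s2$composite_by_k, s1$composite_by_k, tolerance = 1e-9)
  expect_equal(s2$chosen_k, s1$chosen_k)
})

test_that("adding a strictly monotone dummy measure never changes chosen k", {
  h <- planted_histograms(n_diseases = 20, seed = 9)
  v <- build_vectors(h)
  lab <- cluster_solutions(v, methods = c("ward", "kmeans"), k_range = 2:6,
                           seed = 1)
  grid <- score_grid(lab, v, measures = c("silhouette", "dunn"))
  dummy <- do.call(rbind, lapply(c("ward", "kmeans"), function(m)
    data.frame(method = m, k = 2:6, measure = "dummy", score = 2:6,
               failed = FALSE, stringsAsFactors = FALSE)))
  g2 <- rbind(as.data.frame(grid), dummy)
  attr(g2, "k_range") <- attr(grid, "k_range")
  class(g2) <- c("validity_grid", "data.frame")
  base_k <- select_k(remove_monotonic(grid), lab)$chosen_k
  expect_equal(select_k(remove_monotonic(g2), lab)$chosen_k, base_k)
})

test_that("cluster profiles are the elementwise mean of member unit vectors", {
  h <- matrix(0L, 3, 91, dimnames = list(c("a", "b", "c"),
                                         as.character(0:90)))
  h["a", 1:2] <- c(3L, 4L)
  h["b", 1:2] <- c(3L, 4L)
  h["c", 10] <- 5L
  v <- build_vectors(h)
  prof <- cluster_profiles(setNames(c(1L, 1L, 2L), c("a", "b", "c")), h)
  expect_equal(prof["1", ], v["a", ])          # two identical members
  expect_equal(prof["2", ], v["c", ])          # singleton cluster
  prof2 <- cluster_profiles(setNames(c(1L, 1L), c("a", "c")), h)
  expect_equal(prof2["1", ], (v["a", ] + v["c", ]) / 2)  # hand-computed mean
})
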