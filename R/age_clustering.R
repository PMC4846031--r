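#' Unit-normalized age-incidence vectors
#'
#' Each disease is represented as a 91-dimensional vector of earliest-onset
#' counts for ages 0..90, divided by its Euclidean length so that diseases
#' are compared by the *shape* of their incidence curve, not by how common
#' they are.
#'
#' @param histograms Integer matrix, diseases x 91 (as produced by
#'   [count_diseases_and_pairs()]).
#' @return Numeric matrix of the same shape with unit-norm rows.
#' @export
build_vectors <- function(histograms) {
  stopifnot(is.matrix(histograms), ncol(histograms) == 91)
  if (any(histograms < 0)) stop("histogram counts must be nonnegative")
  nrm <- sqrt(rowSums(histograms^2))
  zero <- rownames(histograms)[nrm == 0]
  if (length(zero))
    stop("disease(s) with an all-zero onset histogram: ",
         paste(zero, collapse = ", "))
  histograms / nrm
}

# Fit one clustering method at one k; returns an integer label vector.
fit_labels <- function(x, method, k, nstart = 10, ward_tree = NULL) {
  switch(method,
    ward = {
      if (is.null(ward_tree))
        ward_tree <- stats::hclust(stats::dist(x), method = "ward.D2")
      stats::cutree(ward_tree, k = k)
    },
    kmeans = stats::kmeans(x, centers = k, nstart = nstart,
                           iter.max = 50)$cluster,
    pam = cluster::pam(x, k = k, cluster.only = TRUE),
    stop("unknown clustering method: ", method))
}

#' Cluster the incidence vectors over a grid of methods and cluster counts
#'
#' Ward hierarchical clustering (Euclidean distance on the unit vectors) is
#' always computed from a single tree cut at each k, so its labelings are
#' deterministic; partitional methods (k-means with restarts, k-medoids) use
#' the provided seed.
#'
#' @param vectors Matrix from [build_vectors()].
#' @param methods Subset of `"ward"`, `"kmeans"`, `"pam"`.
#' @param k_range Integer vector of cluster counts to try (default 2:10).
#' @param seed Seed for the partitional methods.
#' @param nstart k-means restarts (default 10).
#' @return Nested list `labelings[[method]][[as.character(k)]]`: named
#'   integer label vectors, each with exactly `k` nonempty clusters.
#' @export
cluster_solutions <- function(vectors, methods = c("ward", "kmeans", "pam"),
                              k_range = 2:10, seed = 1, nstart = 10) {
  stopifnot(length(methods) >= 1, length(k_range) >= 1)
  if (max(k_range) > nrow(vectors))
    stop(sprintf("k = %d exceeds the number of diseases (%d)",
                 max(k_range), nrow(vectors)))
  ward_tree <- stats::hclust(stats::dist(vectors), method = "ward.D2")
  with_seed(seed, {
    out <- lapply(methods, function(m) {
      per_k <- lapply(k_range, function(k) {
        lab <- fit_labels(vectors, m, k, nstart, ward_tree)
        names(lab) <- rownames(vectors)
        lab
      })
      names(per_k) <- as.character(k_range)
      per_k
    })
    names(out) <- methods
    out
  })
}

## ---- internal cluster-validity indices -------------------------------------
## All written against a distance matrix / data matrix; orientation is fixed
## in score_grid so that larger aligned scores mean better clusterings.

index_silhouette <- function(d, labels) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(dm[i, own]) / (sum(own) - 1)
    b <- min(vapply(ks[ks != labels[i]],
                    function(kk) mean(dm[i, labels == kk]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

index_calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (kk in unique(labels)) {
    xi <- x[labels == kk, , drop = FALSE]
    ci <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, ci)^2)
    b <- b + nrow(xi) * sum((ci - grand)^2)
  }
  if (w == 0) return(NA_real_)
  (b / (k - 1)) / (w / (n - k))
}

index_dunn <- function(d, labels) {
  dm <- as.matrix(d)
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  diam <- max(vapply(ks, function(kk) {
    idx <- which(labels == kk)
    if (length(idx) < 2) 0 else max(dm[idx, idx])
  }, 0))
  sep <- min(vapply(seq_along(ks)[-1], function(j) {
    min(vapply(seq_len(j - 1), function(i)
      min(dm[labels == ks[i], labels == ks[j], drop = FALSE]), 0))
  }, 0))
  if (diam == 0) return(NA_real_)
  sep / diam
}

index_davies_bouldin <- function(x, labels) {
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) return(NA_real_)
  cent <- t(vapply(ks, function(kk)
    colMeans(x[labels == kk, , drop = FALSE]), numeric(ncol(x))))
  scat <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, 0)
  db <- vapply(seq_len(k), function(i) {
    r <- vapply(seq_len(k), function(j) {
      if (i == j) return(-Inf)
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (m == 0) Inf else (scat[i] + scat[j]) / m
    }, 0)
    max(r)
  }, 0)
  mean(db)
}

index_connectivity <- function(d, labels, L = 10) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  L <- min(L, n - 1)
  conn <- 0
  for (i in seq_len(n)) {
    nn <- order(dm[i, ])[-1][seq_len(L)]
    mism <- labels[nn] != labels[i]
    conn <- conn + sum((1 / seq_len(L))[mism])
  }
  conn
}

log_wss <- function(x, labels) {
  w <- 0
  for (kk in unique(labels)) {
    xi <- x[labels == kk, , drop = FALSE]
    w <- w + sum(sweep(xi, 2, colMeans(xi))^2)
  }
  log(max(w, .Machine$double.xmin))
}

index_gap <- function(x, labels, method, k, B = 25, nstart = 2) {
  ranges <- apply(x, 2, range)
  # reference draws are clustered with the same method; labelings supplied
  # under a name that is not a fit method fall back to k-means references
  ref_method <- if (method %in% c("ward", "kmeans", "pam")) method else "kmeans"
  ref <- vapply(seq_len(B), function(b) {
    xb <- apply(ranges, 2, function(r)
      stats::runif(nrow(x), r[1], r[2]))
    log_wss(xb, fit_labels(xb, ref_method, k, nstart = nstart))
  }, 0)
  mean(ref) - log_wss(x, labels)
}

#' Score every clustering solution with a panel of validity measures
#'
#' Computes each configured internal validity index for each (method, k)
#' labeling and sign-aligns them so that larger values always indicate a
#' more desirable clustering (Davies–Bouldin and connectivity, where smaller
#' is better, are negated).  Indices that cannot be computed for a labeling
#' (for example a degenerate single-cluster labeling) are marked failed
#' rather than silently dropped.
#'
#' @param labelings From [cluster_solutions()].
#' @param vectors The matrix that was clustered.
#' @param measures Subset of `"silhouette"`, `"calinski_harabasz"`,
#'   `"dunn"`, `"davies_bouldin"`, `"connectivity"`, `"gap"`.
#' @param gap_B Reference draws for the gap statistic (default 25).
#' @param seed Seed for the gap-statistic reference draws.
#' @return data.frame of class `validity_grid` with columns `method`, `k`,
#'   `measure`, `score` (aligned), `failed`.
#' @export
score_grid <- function(labelings, vectors,
                       measures = c("silhouette", "calinski_harabasz",
                                    "dunn", "davies_bouldin",
                                    "connectivity", "gap"),
                       gap_B = 25, seed = 1) {
  known <- c("silhouette", "calinski_harabasz", "dunn", "davies_bouldin",
             "connectivity", "gap")
  bad <- setdiff(measures, known)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  d <- stats::dist(vectors)
  rows <- list()
  with_seed(seed, {
    for (m in names(labelings)) for (kchr in names(labelings[[m]])) {
      labels <- labelings[[m]][[kchr]]
      k <- as.integer(kchr)
      for (meas in measures) {
        sc <- tryCatch(switch(meas,
          silhouette = index_silhouette(d, labels),
          calinski_harabasz = index_calinski_harabasz(vectors, labels),
          dunn = index_dunn(d, labels),
          davies_bouldin = -index_davies_bouldin(vectors, labels),
          connectivity = -index_connectivity(d, labels),
          gap = index_gap(vectors, labels, m, k, B = gap_B)),
          error = function(e) NA_real_)
        if (!is.null(sc) && (is.na(sc) || !is.finite(sc))) sc <- NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, k = k, measure = meas, score = sc,
          failed = is.na(sc), stringsAsFactors = FALSE)
      }
    }
  })
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "k_range") <- sort(unique(grid$k))
  class(grid) <- c("validity_grid", "data.frame")
  grid
}

#' Remove validity measures that are monotone in cluster count
#'
#' A measure whose score is a strictly monotone function of k for *every*
#' method would always be optimized at an end of the search range and so
#' carries no information about the number of clusters; such measures are
#' removed before compositing.  Monotonicity must be strict: a plateau still
#' carries peak information, so non-strict sequences are retained.
#'
#' @param grid A `validity_grid` from [score_grid()].
#' @return The grid restricted to retained measures, with attribute
#'   `removed_measures`.
#' @export
remove_monotonic <- function(grid) {
  stopifnot(inherits(grid, "validity_grid"))
  measures <- unique(grid$measure)
  is_mono <- function(v) {
    if (anyNA(v) || length(v) < 2) return(FALSE)
    dv <- diff(v)
    all(dv > 0) || all(dv < 0)
  }
  removed <- vapply(measures, function(meas) {
    sub <- grid[grid$measure == meas, ]
    all(vapply(unique(sub$method), function(m) {
      s <- sub[sub$method == m, ]
      is_mono(s$score[order(s$k)])
    }, TRUE))
  }, TRUE)
  removed_measures <- measures[removed]
  if (all(removed))
    stop("every validity measure is monotone in k; choose a different measure set")
  out <- grid[!(grid$measure %in% removed_measures), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k_range") <- attr(grid, "k_range")
  attr(out, "removed_measures") <- removed_measures
  class(out) <- c("validity_grid", "data.frame")
  out
}

#' Composite score and locally optimal cluster count
#'
#' Each retained measure is z-standardized (zero mean, unit variance) across
#' all its non-failed (method, k) cells, the standardized scores are averaged
#' per k over methods and measures, and the chosen k is a local maximum of
#' that composite: greater than both neighbors (a boundary k qualifies when
#' greater than its single neighbor).  When several local maxima exist the
#' highest composite wins, with ties broken toward smaller k.  Final labels
#' come from the Ward labeling at the chosen k.
#'
#' @param grid A `validity_grid`, typically after [remove_monotonic()].
#' @param labelings The labelings scored by the grid (must include `"ward"`).
#' @return Object of class `cluster_selection`: `chosen_k`,
#'   `composite_by_k`, `removed_measures`, `final_labels`.
#' @export
select_k <- function(grid, labelings) {
  stopifnot(inherits(grid, "validity_grid"))
  if (!"ward" %in% names(labelings))
    stop("labelings must include the 'ward' method for the final labels")
  g <- grid[!grid$failed, , drop = FALSE]
  if (nrow(g) == 0) stop("no usable validity scores")
  for (meas in unique(g$measure)) {
    idx <- g$measure == meas
    v <- g$score[idx]
    sdv <- stats::sd(v)
    g$score[idx] <- if (is.na(sdv) || sdv == 0) 0 else (v - mean(v)) / sdv
  }
  comp <- tapply(g$score, g$k, mean)
  ks <- as.integer(names(comp))
  ord <- order(ks); ks <- ks[ord]; comp <- as.numeric(comp[ord])
  if (length(unique(comp)) == 1)
    stop("composite score is flat across k; cannot select a cluster count")
  n <- length(comp)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) comp[i] > comp[i - 1] else TRUE
    right <- if (i < n) comp[i] > comp[i + 1] else TRUE
    left && right
  }, TRUE)
  if (!any(is_max))
    stop("no local maximum in the composite score over k")
  cand <- which(is_max)
  best <- cand[comp[cand] == max(comp[cand])]
  chosen_k <- ks[min(best)]
  final <- labelings[["ward"]][[as.character(chosen_k)]]
  if (is.null(final))
    stop("no ward labeling available at the chosen k = ", chosen_k)
  structure(list(chosen_k = chosen_k,
                 composite_by_k = stats::setNames(comp, ks),
                 removed_measures = attr(grid, "removed_measures") %||%
                   character(),
                 final_labels = final),
            class = "cluster_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection: k = %d over k in {%s}>\n", x$chosen_k,
              paste(names(x$composite_by_k), collapse = ", ")))
  if (length(x$removed_measures))
    cat("  removed monotone measures:",
        paste(x$removed_measures, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster mean incidence profile
#'
#' Elementwise mean of the member unit vectors of each cluster — the curve
#' plotted to characterize a cluster's life-stage pattern.
#'
#' @param labels Named cluster labels (or a `cluster_selection`, whose
#'   `final_labels` are used).
#' @param histograms Onset histogram matrix for the labelled diseases.
#' @return Matrix, one row per cluster id, 91 columns (ages 0..90).
#' @export
cluster_profiles <- function(labels, histograms) {
  if (inherits(labels, "cluster_selection")) labels <- labels$final_labels
  vectors <- build_vectors(histograms[names(labels), , drop = FALSE])
  ks <- sort(unique(labels))
  out <- t(vapply(ks, function(kk)
    colMeans(vectors[names(labels)[labels == kk], , drop = FALSE]),
    numeric(91)))
  rownames(out) <- as.character(ks)
  colnames(out) <- as.character(0:90)
  out
}
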