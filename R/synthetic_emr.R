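#' Parametric age-incidence profile for a synthetic disease
#'
#' A disease's earliest-onset-age density over integer ages 0..90, modelled
#' as a mixture of one or two bell-shaped bumps.  Life-stage shapes (neonate,
#' youth, adulthood, aged) are obtained by placing the bump center early or
#' late in life.
#'
#' @param disease_name Text label.
#' @param centers,widths,weights Numeric vectors (length 1 or 2): bump center
#'   age in years, bump standard deviation in years, and mixture weight
#'   (weights are normalized to sum to 1).
#' @param prevalence Baseline probability in (0, 1) that a roster patient
#'   ever acquires the disease.
#' @return Object of class `age_profile` carrying the discretized density
#'   `density` (length 91, sums to 1).
#' @export
age_profile <- function(disease_name, centers, widths, weights = NULL,
                        prevalence) {
  stopifnot(length(centers) %in% 1:2, length(widths) == length(centers),
            all(widths > 0), prevalence > 0, prevalence < 1)
  if (is.null(weights)) weights <- rep(1, length(centers))
  stopifnot(length(weights) == length(centers), all(weights > 0))
  weights <- weights / sum(weights)
  ages <- 0:90
  dens <- numeric(91)
  for (i in seq_along(centers))
    dens <- dens + weights[i] * stats::dnorm(ages, centers[i], widths[i])
  if (sum(dens) <= 0) stop("degenerate age profile for ", disease_name)
  dens <- dens / sum(dens)
  structure(list(disease_name = disease_name, centers = centers,
                 widths = widths, weights = weights,
                 prevalence = prevalence, density = dens),
            class = "age_profile")
}

#' Synthetic-EMR simulation configuration
#'
#' @param n_patients Roster size.
#' @param profiles List of [age_profile()] objects with unique disease names.
#' @param planted_pairs Optional data.frame `disease_a`, `disease_b`,
#'   `risk_multiplier`: for such a pair the joint probability of carrying
#'   both diseases is `risk_multiplier * P(a) * P(b)` (multiplier > 1
#'   synergistic, < 1 protective, 1 independent).  All unplanted pairs are
#'   independent.
#' @param observation_window Integer `(start_year, end_year)` for visit
#'   years.
#' @param seed Integer seed; identical configuration + seed reproduces the
#'   output byte for byte.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients, profiles, planted_pairs = NULL,
                       observation_window = c(2008, 2013), seed = 1) {
  stopifnot(n_patients >= 0, length(observation_window) == 2,
            observation_window[1] <= observation_window[2])
  names(profiles) <- vapply(profiles, `[[`, "", "disease_name")
  if (anyDuplicated(names(profiles)))
    stop("disease names in profiles must be unique")
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(disease_a = character(),
                                disease_b = character(),
                                risk_multiplier = numeric(),
                                stringsAsFactors = FALSE)
  stopifnot(all(c("disease_a", "disease_b", "risk_multiplier") %in%
                names(planted_pairs)))
  if (any(planted_pairs$risk_multiplier <= 0))
    stop("risk multipliers must be positive")
  if (any(planted_pairs$disease_a == planted_pairs$disease_b))
    stop("a planted pair must name two distinct diseases")
  unknown <- setdiff(c(planted_pairs$disease_a, planted_pairs$disease_b),
                     names(profiles))
  if (length(unknown))
    stop("planted pairs reference undeclared disease(s): ",
         paste(unknown, collapse = ", "))
  structure(list(n_patients = as.integer(n_patients), profiles = profiles,
                 planted_pairs = planted_pairs,
                 observation_window = as.integer(observation_window),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Validate and return the joint 2x2 probabilities for a planted pair.
pair_joint <- function(pa, pb, rho, label) {
  p11 <- rho * pa * pb
  if (p11 > min(pa, pb) || pa + pb - p11 > 1)
    stop(sprintf(
      "planted pair %s: joint probability %.4g is infeasible for marginals %.4g / %.4g",
      label, p11, pa, pb))
  c(p00 = 1 - pa - pb + p11, p01 = pb - p11, p10 = pa - p11, p11 = p11)
}

#' Draw the patient-by-disease incidence matrix
#'
#' Sequential conditional sampling: planted pairs are drawn (in declaration
#' order) from their marginal-preserving joint; a disease already decided by
#' an earlier pair is conditioned on rather than redrawn; all remaining
#' diseases are independent Bernoulli draws at their baseline prevalence.
#'
#' @param config A [sim_config()].
#' @return Logical matrix `n_patients x diseases`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    diseases <- names(config$profiles)
    n <- config$n_patients
    prev <- vapply(config$profiles, `[[`, 0, "prevalence")
    has <- matrix(FALSE, n, length(diseases),
                  dimnames = list(NULL, diseases))
    decided <- setNames(rep(FALSE, length(diseases)), diseases)
    pp <- config$planted_pairs
    for (i in seq_len(nrow(pp))) {
      a <- pp$disease_a[i]; b <- pp$disease_b[i]
      lab <- paste(a, b, sep = " / ")
      jp <- pair_joint(prev[[a]], prev[[b]], pp$risk_multiplier[i], lab)
      if (!decided[a] && !decided[b]) {
        if (n > 0) {
          cell <- sample.int(4L, n, replace = TRUE, prob = jp)
          has[, a] <- cell %in% c(3L, 4L)
          has[, b] <- cell %in% c(2L, 4L)
        }
        decided[c(a, b)] <- TRUE
      } else if (xor(decided[a], decided[b])) {
        first <- if (decided[a]) a else b
        second <- if (decided[a]) b else a
        pf <- prev[[first]]
        p_given1 <- jp[["p11"]] / pf
        p_given0 <- (prev[[second]] - jp[["p11"]]) / (1 - pf)
        pr <- ifelse(has[, first], p_given1, p_given0)
        if (n > 0) has[, second] <- stats::runif(n) < pr
        decided[second] <- TRUE
      } else {
        stop(sprintf(
          "planted pair %s: both diseases already constrained by earlier pairs",
          lab))
      }
    }
    for (dn in diseases[!decided])
      if (n > 0) has[, dn] <- stats::runif(n) < prev[[dn]]
    has
  })
}

#' Simulate encounter-level records for one EMR source
#'
#' Draws the cohort incidence matrix, samples each patient-disease onset age
#' from the disease's discretized age profile (independently of co-disease
#' status), and emits encounter rows.  Each disease is given two synthetic
#' ICD9-style codes; the onset encounter uses one of them and, with
#' probability 1/2, a second later-age encounter (possibly under the other
#' code) is added so that downstream earliest-onset reduction is exercised.
#' Ages are integer years censored at 90.
#'
#' @param config A [sim_config()].
#' @return list with `encounters` (data.frame `patient_id`, `icd9`,
#'   `age_at_visit`, `visit_year`), `catalog` (named vector icd9 -> disease),
#'   `cohort` (the incidence matrix), and `truth` (ground-truth summary:
#'   per-disease prevalence and the planted pairs with multipliers).
#' @export
simulate_emr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_cohort(config)
  diseases <- colnames(cohort)
  codes <- stats::setNames(
    sprintf("%03d.%d", rep(seq_along(diseases), each = 2), 0:1),
    rep(diseases, each = 2))
  catalog <- stats::setNames(names(codes), codes)  # icd9 -> disease
  enc <- with_seed(config$seed + 1L, {
    rows <- vector("list", length(diseases))
    for (j in seq_along(diseases)) {
      ids <- which(cohort[, j])
      if (!length(ids)) next
      dn <- diseases[j]
      onset <- sample(0:90, length(ids), replace = TRUE,
                      prob = config$profiles[[dn]]$density)
      yr <- sample(config$observation_window[1]:config$observation_window[2],
                   length(ids), replace = TRUE)
      code1 <- unname(codes[names(codes) == dn][1])
      code2 <- unname(codes[names(codes) == dn][2])
      first <- data.frame(patient_id = sprintf("P%07d", ids),
                          icd9 = sample(c(code1, code2), length(ids),
                                        replace = TRUE),
                          age_at_visit = onset, visit_year = yr,
                          stringsAsFactors = FALSE)
      again <- stats::runif(length(ids)) < 0.5
      rep_rows <- data.frame(
        patient_id = first$patient_id[again],
        icd9 = sample(c(code1, code2), sum(again), replace = TRUE),
        age_at_visit = pmin(90L, onset[again] +
                              sample(1:3, sum(again), replace = TRUE)),
        visit_year = yr[again], stringsAsFactors = FALSE)
      rows[[j]] <- rbind(first, rep_rows)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(out))
      out <- data.frame(patient_id = character(), icd9 = character(),
                        age_at_visit = integer(), visit_year = integer(),
                        stringsAsFactors = FALSE)
    out[order(out$patient_id, out$icd9, out$age_at_visit), , drop = FALSE]
  })
  rownames(enc) <- NULL
  truth <- list(prevalence = vapply(config$profiles, `[[`, 0, "prevalence"),
                planted_pairs = config$planted_pairs,
                n_patients = config$n_patients)
  list(encounters = enc, catalog = catalog, cohort = cohort, truth = truth)
}

#' Pair-count table straight from a simulated cohort
#'
#' Convenience shortcut that skips encounter emission and earliest-onset
#' reduction: counts diseases and pairs directly on the incidence matrix.
#' Useful for large replicate studies of the testing stage.
#'
#' @param config A [sim_config()].
#' @param source_label Label for the resulting table.
#' @return A [pair_count_table()].
#' @export
simulate_pair_counts <- function(config, source_label = "sim") {
  cohort <- simulate_cohort(config)
  cohort_pair_counts(cohort, source_label)
}

# counts from an incidence matrix (crossprod gives all pairwise d_ij)
cohort_pair_counts <- function(cohort, source_label = "sim") {
  m <- crossprod(cohort * 1L)
  diseases <- colnames(cohort)
  counts <- stats::setNames(diag(m), diseases)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  pc <- data.frame(disease1 = diseases[idx[, 1]],
                   disease2 = diseases[idx[, 2]],
                   count = m[idx], stringsAsFactors = FALSE)
  pair_count_table(nrow(cohort), counts, pc, source_label)
}

#' Write simulated EMR output as delimited text
#'
#' @param sim Result of [simulate_emr()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `encounters.csv`, `catalog.csv`,
#'   `ground_truth.txt` (key-value lines).
#' @export
write_sim_emr <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("encounters.csv", "catalog.csv",
                            "ground_truth.txt"))
  utils::write.csv(sim$encounters, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(icd9 = names(sim$catalog),
                              disease = unname(sim$catalog)),
                   paths[2], row.names = FALSE, quote = FALSE)
  tr <- sim$truth
  lines <- c(sprintf("n_patients\t%d", tr$n_patients),
             sprintf("prevalence\t%s\t%g", names(tr$prevalence),
                     tr$prevalence),
             if (nrow(tr$planted_pairs))
               sprintf("planted_pair\t%s\t%s\t%g", tr$planted_pairs$disease_a,
                       tr$planted_pairs$disease_b,
                       tr$planted_pairs$risk_multiplier))
  writeLines(lines, paths[3])
  invisible(paths)
}
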