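# Shared fixture builders: everything is generated in code at test time.

# Onset histograms for `n_diseases` diseases drawn from 4 well-separated
# life-stage profiles (centers 5/25/50/75 years, sd 5), with a small
# per-disease jitter of the center so within-group vectors are similar but
# not identical.
planted_histograms <- function(n_diseases = 40, n_per_disease = 300,
                               seed = 1) {
  centers <- c(5, 25, 50, 75)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    hist <- matrix(0L, n_diseases, 91,
                   dimnames = list(sprintf("D%02d", seq_len(n_diseases)),
                                   as.character(0:90)))
    truth <- integer(n_diseases)
    for (i in seq_len(n_diseases)) {
      g <- (i - 1) %% 4 + 1
      truth[i] <- g
      pr <- age_profile(rownames(hist)[i], centers[g] + runif(1, -2, 2), 5,
                        prevalence = 0.01)
      hist[i, ] <- as.integer(rmultinom(1, n_per_disease, pr$density))
    }
    attr(hist, "truth") <- truth
    hist
  })
}

# A small null cohort configuration (no planted pairs).
null_config <- function(n_patients, n_diseases = 20, seed = 1,
                        prev_range = c(0.02, 0.06)) {
  prev <- seq(prev_range[1], prev_range[2], length.out = n_diseases)
  profiles <- lapply(seq_len(n_diseases), function(i)
    age_profile(sprintf("D%02d", i), centers = 40, widths = 15,
                prevalence = prev[i]))
  sim_config(n_patients, profiles, seed = seed)
}

# Two diseases with a planted multiplier plus independent fillers.
planted_pair_config <- function(n_patients, rho, marginal = 0.02, seed = 1) {
  profiles <- list(
    age_profile("A", 40, 10, prevalence = marginal),
    age_profile("B", 45, 10, prevalence = marginal),
    age_profile("C", 30, 10, prevalence = 0.03),
    age_profile("D", 50, 10, prevalence = 0.03),
    age_profile("E", 60, 10, prevalence = 0.03))
  sim_config(n_patients, profiles,
             planted_pairs = data.frame(disease_a = "A", disease_b = "B",
                                        risk_multiplier = rho),
             seed = seed)
}

# A synthetic variant table with planted set sizes and pairwise overlaps,
# written to a temporary CSV in the schema of a pre-filtered association
# table (no p_value column).
write_variant_fixture <- function(config, path = tempfile(fileext = ".csv")) {
  tab <- simulate_variants(config)
  utils::write.csv(tab, path, row.names = FALSE)
  path
}

# Independent oracle for the two-sided Fisher p: direct dhyper enumeration
# with the same as-or-less-probable rule.
fisher_oracle <- function(n1, n2, d, N) {
  lo <- max(0, n1 + n2 - N); hi <- min(n1, n2)
  k <- lo:hi
  pk <- stats::dhyper(k, n1, N - n1, n2)
  vapply(d, function(di) min(1, sum(pk[pk <= pk[di - lo + 1] * (1 + 1e-7)])),
         numeric(1))
}
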