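#' Fisher exact test for a 2x2 disease-pair table
#'
#' Exact hypergeometric test on the co-occurrence cell of a 2x2 contingency
#' table with fixed margins, computed in log space so that it is stable at
#' roster sizes around 10^6.  The two-sided p-value is the classical
#' "sum of as-or-less-probable tables": all tables sharing the observed
#' margins whose point probability does not exceed that of the observed table
#' (with a relative tolerance of 1e-7 on the comparison, so the observed
#' table is never excluded by floating-point error).  The one-sided
#' `"greater"` alternative is the upper-tail sum used for enrichment.
#'
#' @param n1,n2 Marginal patient counts for the two diseases.
#' @param d Observed count of patients with both diseases (may be a vector).
#' @param N Roster total.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return p-value(s) in (0, 1].  Degenerate margins (a zero row or column
#'   total) give p = 1.
#' @seealso [build_table()], [obs_exp_ratio()]
#' @export
fisher_exact_p <- function(n1, n2, d, N,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(n1) == 1, length(n2) == 1, length(N) == 1)
  if (n1 < 0 || n2 < 0 || N < 0) stop("counts must be nonnegative")
  if (n1 > N || n2 > N) stop("marginal count exceeds roster total N")
  lo <- max(0L, n1 + n2 - N)
  hi <- min(n1, n2)
  if (any(d < lo | d > hi))
    stop("observed both-disease count outside the hypergeometric support")
  # degenerate margins: only one table is possible
  if (n1 == 0L || n2 == 0L || n1 == N || n2 == N)
    return(rep(1, length(d)))
  k <- lo:hi
  logp <- lchoose(n1, k) + lchoose(N - n1, n2 - k) - lchoose(N, n2)
  logsumexp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }
  vapply(d, function(di) {
    i <- di - lo + 1L
    p <- switch(alternative,
      two.sided = {
        keep <- logp <= logp[i] + log1p(1e-7)
        logsumexp(logp[keep])
      },
      greater = logsumexp(logp[k >= di]),
      less = logsumexp(logp[k <= di]))
    min(1, exp(p))
  }, numeric(1))
}

#' @rdname fisher_exact_p
#' @param table A `contingency_table` from [build_table()].
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  fisher_exact_p(table$n1, table$n2, table$d, table$N, "two.sided")
}
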