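#' @importFrom stats kmeans hclust cutree dist runif rbinom setNames
#' @importFrom utils read.csv write.csv head
#' @import data.table
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not clobber user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Canonical unordered disease-pair key
#'
#' Orders the two disease names lexicographically so that an unordered pair
#' has one deterministic representation across sources and joins.
#'
#' @param d1,d2 Character vectors of disease names (recycled together).
#' @return A two-column data.frame `disease1`, `disease2` with
#'   `disease1 <= disease2` rowwise.
#' @export
canonical_pair <- function(d1, d2) {
  d1 <- as.character(d1); d2 <- as.character(d2)
  swap <- d1 > d2
  tmp <- d1[swap]; d1[swap] <- d2[swap]; d2[swap] <- tmp
  data.frame(disease1 = d1, disease2 = d2, stringsAsFactors = FALSE)
}

pair_id <- function(d1, d2) {
  p <- canonical_pair(d1, d2)
  paste(p$disease1, p$disease2, sep = "\x1f")
}
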