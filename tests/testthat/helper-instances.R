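# Random model generators used across the suite.
#
# Parameters are dyadic rationals (small integers over powers of two) so that
# sums over equiprobable enumeration supports are exact in double precision;
# "exact" comparisons then use a 1e-12 tolerance that only absorbs the final
# division by the support size.

random_dyadic_hane <- function(n, edge_prob = 0.25, seed = 1) {
  set.seed(seed)
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < edge_prob
  edges <- NULL
  if (any(keep)) {
    edges <- pairs[keep, ]
    edges$gamma <- sample(c(-8:-1, 1:8), sum(keep), replace = TRUE) / 8
  }
  hane_model(alpha = sample(-8:8, n, replace = TRUE) / 4,
             beta = sample(-8:8, n, replace = TRUE) / 4,
             edges = edges)
}

random_contracting_contagion <- function(n, seed = 1, scale = 0.6) {
  set.seed(seed)
  pairs <- expand.grid(source = seq_len(n), target = seq_len(n))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < 0.3
  edges <- NULL
  if (any(keep)) {
    edges <- pairs[keep, ]
    # row sums below `scale` keep the spectral radius well under 1
    edges$c <- stats::runif(sum(keep), -1, 1)
    rs <- tapply(abs(edges$c), edges$target, sum)
    norm <- rs[as.character(edges$target)]
    edges$c <- edges$c / pmax(1, norm / scale)
  }
  contagion_model(a = stats::rnorm(n), b = stats::rnorm(n), edges = edges)
}

exact_tol <- 1e-12
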