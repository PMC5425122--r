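# Independent brute-force oracles used to check the pipeline's statistics.

# Quantile normalization by explicit sort / average / reassign, averaging
# reference values over tied ranks.
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- vapply(r, function(ri) {
      if (ri == round(ri)) ref[ri]
      else mean(ref[c(floor(ri), ceiling(ri))])
    }, numeric(1))
  }
  out
}

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1, mapped back.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail P(X >= k) by direct pmf summation with choose().
hyper_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Exact two-sided rank-sum p by full enumeration of all assignments of the
# pooled (untied) values to the two groups.
ranksum_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  all_w <- apply(utils::combn(length(pooled), nx), 2,
                 function(idx) sum(r[idx]))
  p <- 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))
  min(1, p)
}

# Small random expression matrix with named dims.
rand_expr <- function(nr, nc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expression_matrix(matrix(rnorm(nr * nc, mean = 8), nr, nc),
                    sprintf("p%03d", seq_len(nr)),
                    sprintf("s%03d", seq_len(nc)))
}

# Metadata for a given age vector.
meta_for <- function(ages, ids = sprintf("s%03d", seq_along(ages))) {
  data.frame(sample_id = ids, age = ages, stringsAsFactors = FALSE)
}
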