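# Independent oracles used across tests. Each is a literal, unoptimized
# transcription of the defining formula, kept deliberately separate from
# the package's implementations.

# Benjamini-Hochberg step-up, straight from the definition:
# sort ascending, adj_(i) = min over k >= i of min(1, p_(k) * m / k),
# returned in input order.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(pmin(1, sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Weighted KS enrichment score by full prefix-sum enumeration: walk the
# ranked list, +|s|/sum_set|s| on a hit, -1/(N-K) on a miss; ES is the
# running-sum value of maximal absolute deviation.
es_brute_force <- function(scores, is_hit) {
  n <- length(scores)
  k <- sum(is_hit)
  sw <- sum(abs(scores[is_hit]))
  run <- numeric(n)
  acc <- 0
  for (j in seq_len(n)) {
    acc <- acc + if (is_hit[j]) abs(scores[j]) / sw else -1 / (n - k)
    run[j] <- acc
  }
  run[which.max(abs(run))]
}

# small random ranked list for GSEA tests
random_ranked <- function(n, seed) {
  set.seed(seed)
  de <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                   log2fc = rnorm(n), p = runif(n))
  rank_metric(de)
}
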