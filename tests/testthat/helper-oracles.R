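# Independent oracles and shared fixtures. All expected values asserted in
# the suite against these oracles are computed here, not by the code paths
# under test.

# Brute-force enrichment tail by exhaustive enumeration: draw every possible
# K-subset of a universe of N genes, take the pathway to be the first n
# genes, and count the fraction of subsets sharing at least k genes with it.
# All counts are integers well below 2^53, so the result is exact.
enum_tail_pvalue <- function(k, K, n, N) {
  stopifnot(n <= N, K <= N, k <= min(n, K))
  subsets <- utils::combn(N, K)
  overlaps <- colSums(subsets <= n)
  sum(overlaps >= k) / ncol(subsets)
}

# Uniform integer draw on [a, b] immune to sample()'s length-1 surprise.
rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

# log P(X <= k - 1): the complement of the enrichment tail on the log
# scale, so it stays meaningful even when the complement underflows double
# range (upper tail within 1e-308 of 1).
log_lower_tail <- function(k, K, n, N) {
  lo <- max(0, n + K - N)
  if (k - 1 < lo) return(-Inf)
  i <- lo:(k - 1)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

# Strict size monotonicity at fixed (N, K, k), checked on whichever side of
# the distribution carries floating-point precision: the upper tails when
# they are small, their log-scale complements when the tails approach 1.
smaller_pathway_wins <- function(k, K, n1, n2, N) {
  p2 <- enrichment_pvalue(k, K, n2, N)
  if (p2 <= 0.5) {
    enrichment_pvalue(k, K, n1, N) < p2
  } else {
    log_lower_tail(k, K, n1, N) > log_lower_tail(k, K, n2, N)
  }
}

# Naive critical-subset solver: scan every k from 1 upward.
scan_critical_k <- function(n, N, K, threshold) {
  for (k in seq_len(min(n, K))) {
    if (enrichment_pvalue(k, K, n, N) <= threshold) return(k)
  }
  NA_integer_
}

# Two small hand-built databases reused across files.
toy_db <- function() {
  pathway_db(
    list(pwA = c("g1", "g2", "g3"), pwB = c("g3", "g4", "g5", "g6")),
    name = "toy"
  )
}

# A fine database whose pathway-assigned total is exactly 1096: one 3-gene
# pathway of interest plus one bulk pathway covering the rest.
ecocyc_scale_db <- function() {
  pathway_db(
    list(
      target = c("g0001", "g0002", "g0003"),
      bulk = sprintf("g%04d", 4:1096)
    ),
    name = "ecocyc_scale"
  )
}
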