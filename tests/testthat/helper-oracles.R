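# Independent brute-force oracles, written from the definitions and kept
# free of the package's own vectorized implementations.

# KS enrichment by an explicit O(N) cumulative walk over the whole list.
# is_hit: logical over ranked positions; eff: effective values in rank order
# (only used for weighted increments). Returns the signed deviation of
# maximal absolute value (positive branch wins an exact tie).
ksWalkOracle <- function(is_hit, eff = NULL,
                         weighting = c("classic", "weighted")) {
  weighting <- match.arg(weighting)
  N <- length(is_hit)
  m <- sum(is_hit)
  stopifnot(m > 0L, m < N)
  w <- rep(0, N)
  if (weighting == "classic") {
    w[is_hit] <- 1
  } else {
    w[is_hit] <- abs(eff[is_hit])
    if (sum(w) == 0) w[is_hit] <- 1
  }
  w <- w / sum(w)
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    run <- if (is_hit[i]) run + w[i] else run - 1 / (N - m)
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  # tie convention as documented: +/- ties resolve to the positive branch
  if (hi >= -lo - 1e-12) hi else lo
}

# AUC as the probability of concordance over all positive-negative pairs,
# ties counted 1/2 (the Mann-Whitney U normalization), by full enumeration.
aucConcordanceOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Two-sided permutation p-value for a two-group comparison, using the
# studentized (Welch-type) statistic so group-size imbalance is accounted
# for; the null distribution is built by relabeling, not from a t reference.
permutationPOracle <- function(x, g, B = 10000L) {
  welch_t <- function(a, b)
    (mean(a) - mean(b)) /
      sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  obs <- abs(welch_t(x[g], x[!g]))
  n1 <- sum(g)
  cnt <- 0L
  for (b in seq_len(B)) {
    gp <- seq_along(x) %in% sample(seq_along(x), n1)
    if (abs(welch_t(x[gp], x[!gp])) >= obs) cnt <- cnt + 1L
  }
  (cnt + 1L) / (B + 1L)
}

# Descending stable sort with lexicographic id tie-break: the plain-sort
# oracle for ranking when every probe is Present.
plainDescendingOracle <- function(v) {
  names(v)[order(-v, names(v), method = "radix")]
}
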