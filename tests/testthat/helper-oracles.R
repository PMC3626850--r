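# Independently coded brute-force oracles. These deliberately avoid the
# package's implementation paths: explicit loops, closed-form textbook
# formulas, or exhaustive enumeration at tiny n.

oracle_quantile_normalize <- function(mat) {
  n <- nrow(mat)
  ref <- numeric(n)
  for (j in seq_len(ncol(mat))) ref <- ref + sort(mat[, j])
  ref <- ref / ncol(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    for (i in seq_len(n)) {
      span <- which(sort(x) == x[i])     # rank span of (possibly tied) value
      out[i, j] <- mean(ref[span])
    }
  }
  out
}

oracle_median_smooth <- function(x, window = 3) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- sort(x[max(1, i - h):min(n, i + h)])
    m <- length(w)
    out[i] <- if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }
  out
}

# textbook paired two-tailed Student t
oracle_paired_t_p <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n))
  2 * stats::pt(-abs(t_stat), df = n - 1)
}

# Spearman distance from first principles: average ranks, then the Pearson
# product-moment formula on the ranks.
oracle_spearman_distance <- function(mat) {
  n <- nrow(mat)
  rk <- t(apply(mat, 1, rank))
  d <- matrix(0, n, n)
  if (!is.null(rownames(mat)))
    dimnames(d) <- list(rownames(mat), rownames(mat))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- rk[i, ]; b <- rk[j, ]
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    d[i, j] <- 1 - num / den
  }
  diag(d) <- 0
  d
}

# exhaustive hypergeometric tails: enumerate all size-n subsets of an
# N-element universe (N <= 12) and count overlaps with the annotated set
oracle_hyper_tails <- function(k, K, N, n) {
  combos <- utils::combn(N, n)
  overlap <- colSums(combos <= K)   # annotated items are 1..K
  list(over = mean(overlap >= k), under = mean(overlap <= k))
}
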