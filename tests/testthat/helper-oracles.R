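# Independent oracles, deliberately written as plain transcriptions of the
# defining formulas (loops, no shared code with the package internals).

# Biweight midcorrelation of two complete vectors.
bicor_oracle <- function(x, y) {
  tf <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) return(v - mean(v))
    u <- (v - med) / (9 * madv)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    (v - med) * w
  }
  ok <- !is.na(x) & !is.na(y)
  a <- tf(x[ok]); b <- tf(y[ok])
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Topological overlap by explicit loops over the defining sum.
tom_oracle <- function(a) {
  p <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(1, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    num <- 0
    for (u in seq_len(p)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    out[i, j] <- (num + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Rank-sum burden score by two explicit loops.
ranksum_oracle <- function(ce) {
  n <- nrow(ce)
  score <- numeric(n)
  for (j in seq_len(ncol(ce))) {
    r <- rank(ce[, j], ties.method = "average")
    for (i in seq_len(n)) score[i] <- score[i] + r[i]
  }
  setNames(score, rownames(ce))
}

# Benjamini-Hochberg q-values from the brute-force step-up definition:
# with p sorted ascending, q_(i) = min(1, min_{j >= i} m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m),
                     function(i) min(1, min(m * ps[i:m] / (i:m))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Alternating-median-polish normalization oracle, iterated to convergence.
tampor_oracle <- function(x, batch, is_ref, iters = 500) {
  for (it in seq_len(iters)) {
    for (b in unique(batch)) {
      sel <- batch == b
      med <- apply(x[, sel & is_ref, drop = FALSE], 1, median, na.rm = TRUE)
      x[, sel] <- x[, sel, drop = FALSE] - med
    }
    x <- sweep(x, 2, apply(x, 2, median, na.rm = TRUE))
  }
  x
}

# Small planted-cluster CE-like matrix for subtyping tests.
make_planted_clusters <- function(n_per = 10, p = 8, sep = 4, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- c(0, sep, 2 * sep)
  lab <- rep(1:3, each = n_per)
  x <- matrix(rnorm(3 * n_per * p, mean = centers[lab], sd = sd), 3 * n_per, p)
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("CE%d", seq_len(p))
  list(x = x, labels = lab)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
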