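# Independent oracles used across the suite. These deliberately use naive
# algorithms (dynamic programming, exhaustive enumeration, direct summation)
# so they share no code path with the implementation they check.

# Exact 1-D k-means optimum by dynamic programming over sorted values.
dp_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs1 <- cumsum(x); cs2 <- cumsum(x^2)
  seg <- function(i, j) {
    s1 <- cs1[j] - if (i > 1) cs1[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s1^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- seg(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        D[q, j] <- min(vapply(q:j, function(i) D[q - 1, i - 1] + seg(i, j),
                              numeric(1)))
      }
    }
  }
  D[k, n]
}

# Brute-force GLCM by per-pixel pair enumeration.
glcm_oracle <- function(lev, offsets, L) {
  d <- dim(lev)
  if (length(d) == 2) { lev <- array(lev, c(d, 1)); d <- dim(lev) }
  counts <- matrix(0, L, L)
  for (z in seq_len(d[3])) for (r in seq_len(d[1])) for (cc in seq_len(d[2]))
    for (off in offsets) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
      a <- lev[r, cc, z]; b <- lev[r2, c2, z]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  if (sum(counts) == 0)
    return(c(contrast = NA_real_, correlation = NA_real_,
             energy = NA_real_, homogeneity = NA_real_))
  p <- counts / sum(counts)
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu <- sum(seq_len(L) * pi_)
  s2 <- sum((seq_len(L) - mu)^2 * pi_)
  corr <- if (s2 > 0) sum(p * (i - mu) * (j - mu)) / s2 else 0
  c(contrast = sum(p * (i - j)^2), correlation = corr,
    energy = sum(p^2), homogeneity = sum(p / (1 + abs(i - j))))
}

# Best achievable depth-1 SSE by exhaustive (feature, midpoint) enumeration.
best_stump_sse <- function(x, r, min_leaf = 1) {
  x <- as.matrix(x)
  best <- sum((r - mean(r))^2)
  for (f in seq_len(ncol(x))) {
    v <- sort(unique(x[, f]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      l <- r[x[, f] <= t]; rr <- r[x[, f] > t]
      if (length(l) < min_leaf || length(rr) < min_leaf) next
      sse <- sum((l - mean(l))^2) + sum((rr - mean(rr))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Pair-counting AUC (ties 1/2) by explicit enumeration.
auc_pairs <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}
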