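# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, sharing no code with the implementation they check.

# All 26 unit offsets, written out without reusing package internals
oracle_offsets <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

# GLCM by exhaustive enumeration over every voxel and offset
oracle_glcm <- function(levels, mask, G) {
  d <- dim(levels)
  acc <- matrix(0, G, G)
  n_used <- 0L
  for (off in oracle_offsets()) {
    cnt <- matrix(0, G, G)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!mask[x, y, z]) next
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      if (!mask[x2, y2, z2]) next
      a <- levels[x, y, z]; b <- levels[x2, y2, z2]
      cnt[a, b] <- cnt[a, b] + 1
    }
    sym <- cnt + t(cnt)
    if (sum(sym) > 0) {
      acc <- acc + sym / sum(sym)
      n_used <- n_used + 1L
    }
  }
  acc / n_used
}

# run enumeration along one direction by walking every line voxel by voxel
oracle_runs <- function(levels, mask, dir) {
  d <- dim(levels)
  inside <- function(p) all(p >= 1) && all(p <= d)
  runs <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (!mask[x, y, z]) next
    prev <- p - dir
    starts <- !inside(prev) || !mask[prev[1], prev[2], prev[3]] ||
      levels[prev[1], prev[2], prev[3]] != levels[x, y, z]
    if (!starts) next
    len <- 1L
    q <- p + dir
    while (inside(q) && mask[q[1], q[2], q[3]] &&
           levels[q[1], q[2], q[3]] == levels[x, y, z]) {
      len <- len + 1L
      q <- q + dir
    }
    runs[[length(runs) + 1L]] <- c(levels[x, y, z], len)
  }
  if (length(runs) == 0L) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, runs)
}

oracle_glrlm_matrix <- function(levels, mask, dir, G) {
  rr <- oracle_runs(levels, mask, dir)
  Rmax <- max(rr[, 2])
  P <- matrix(0, G, Rmax)
  for (i in seq_len(nrow(rr))) {
    P[rr[i, 1], rr[i, 2]] <- P[rr[i, 1], rr[i, 2]] + 1
  }
  P
}

# population skewness/kurtosis by the textbook moment formulas
oracle_skew <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  (sum((v - m)^3) / n) / m2^(3 / 2)
}
oracle_kurt <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  (sum((v - m)^4) / n) / m2^2
}

# PCA scores via an explicit covariance eigendecomposition of the
# training-standardised matrix
oracle_pca_scores <- function(X, train) {
  mu <- colMeans(X[train, , drop = FALSE])
  sdv <- apply(X[train, , drop = FALSE], 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  C <- cov(Z[train, , drop = FALSE])
  e <- eigen(C, symmetric = TRUE)
  list(scores = Z %*% e$vectors, values = e$values)
}

# Holm step-down adjustment written from the definition
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# single-purpose GLCM feature formulas (independent re-derivations)
oracle_glcm_contrast <- function(m) {
  G <- nrow(m); s <- 0
  for (i in 1:G) for (j in 1:G) s <- s + m[i, j] * (i - j)^2
  s
}
oracle_glcm_correlation <- function(m) {
  G <- nrow(m)
  pi_ <- rowSums(m); pj_ <- colSums(m)
  mi <- sum((1:G) * pi_); mj <- sum((1:G) * pj_)
  si <- sqrt(sum((1:G - mi)^2 * pi_)); sj <- sqrt(sum((1:G - mj)^2 * pj_))
  s <- 0
  for (i in 1:G) for (j in 1:G) s <- s + (i - mi) * (j - mj) * m[i, j]
  s / (si * sj)
}
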