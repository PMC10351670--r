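# 26 unit neighbourhood offsets (all 3D neighbours at Chebyshev distance 1)
# and the 13 sign-unique directions used for run-length analysis.
offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

directions_13 <- function() {
  o <- offsets_26()
  keep <- apply(o, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  o[keep, , drop = FALSE]
}

# Co-occurrence counts of in-mask level pairs at one integer offset
# (one-directional; both endpoints must be inside the mask).
glcm_counts_offset <- function(levels, offset, G) {
  d <- dim(levels)
  idx <- vector("list", 3)
  idx2 <- vector("list", 3)
  for (a in 1:3) {
    o <- offset[a]
    if (o >= 0) {
      if (d[a] - o < 1) return(matrix(0, G, G))
      idx[[a]] <- seq_len(d[a] - o)
    } else {
      if (d[a] + o < 1) return(matrix(0, G, G))
      idx[[a]] <- seq(1 - o, d[a])
    }
    idx2[[a]] <- idx[[a]] + o
  }
  a1 <- levels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  a2 <- levels[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
  ok <- !is.na(a1) & !is.na(a2)
  if (!any(ok)) return(matrix(0, G, G))
  counts <- tabulate((a1[ok] - 1L) * G + a2[ok], nbins = G * G)
  matrix(counts, G, G, byrow = TRUE)
}

#' Grey-level co-occurrence matrix (3D, 26 directions averaged)
#'
#' For each of the 26 unit offsets, counts pairs of in-mask voxels at that
#' offset (pairs with an endpoint outside the mask are skipped), symmetrises
#' the count matrix, normalises it to sum 1 and averages the 26 matrices.
#'
#' @param d_roi A [discretized_roi()].
#' @return A G x G symmetric matrix summing to 1.
#' @export
glcm <- function(d_roi) {
  stopifnot(inherits(d_roi, "discretized_roi"))
  G <- d_roi$n_levels
  offs <- offsets_26()
  acc <- matrix(0, G, G)
  n_used <- 0L
  for (r in seq_len(nrow(offs))) {
    cnt <- glcm_counts_offset(d_roi$levels, offs[r, ], G)
    sym <- cnt + t(cnt)
    tot <- sum(sym)
    if (tot > 0) {
      acc <- acc + sym / tot
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("ROI too small: no valid voxel pairs", call. = FALSE)
  acc / n_used
}

#' GLCM texture features
#'
#' Standard co-occurrence features computed from a normalised G x G matrix
#' (IBSI-style definitions): contrast sum p(i,j)(i-j)^2, dissimilarity
#' sum p|i-j|, homogeneity (inverse difference) sum p/(1+|i-j|), inverse
#' difference moment sum p/(1+(i-j)^2), angular second moment / energy
#' sum p^2, Shannon entropy (bits), correlation, autocorrelation sum i*j*p,
#' cluster shade and prominence (third/fourth moments of i+j about its mean)
#' and maximum probability.
#'
#' @param m Normalised G x G co-occurrence matrix.
#' @return Named numeric vector (prefix `glcm_`).
#' @export
glcm_features <- function(m) {
  G <- nrow(m)
  stopifnot(ncol(m) == G, abs(sum(m) - 1) < 1e-8)
  i <- row(m); j <- col(m)
  pi_m <- rowSums(m); pj_m <- colSums(m)
  mu_i <- sum(seq_len(G) * pi_m); mu_j <- sum(seq_len(G) * pj_m)
  sd_i <- sqrt(sum((seq_len(G) - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((seq_len(G) - mu_j)^2 * pj_m))
  pos <- m > 0
  ent <- -sum(m[pos] * log2(m[pos]))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * m) / (sd_i * sd_j)
  } else 0
  out <- c(
    glcm_contrast = sum(m * (i - j)^2),
    glcm_dissimilarity = sum(m * abs(i - j)),
    glcm_homogeneity = sum(m / (1 + abs(i - j))),
    glcm_idm = sum(m / (1 + (i - j)^2)),
    glcm_asm = sum(m^2),
    glcm_entropy = ent,
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * m),
    glcm_cluster_shade = sum((i + j - mu_i - mu_j)^3 * m),
    glcm_cluster_prominence = sum((i + j - mu_i - mu_j)^4 * m),
    glcm_max_probability = max(m)
  )
  attr(out, "family") <- rep("glcm", length(out))
  out
}
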