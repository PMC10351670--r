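# Enumerate maximal same-level runs along one direction within the mask.
# Runs are broken by the grid edge, the mask boundary and level changes.
# Returns a data.frame with columns level, length.
glrlm_runs_direction <- function(levels, mask, dir) {
  d <- dim(levels)
  idx <- which(mask)
  if (length(idx) == 0L) return(data.frame(level = integer(), length = integer()))
  co <- arrayInd(idx, d)
  # parameter along the line: coordinate on the first moving axis, signed so
  # that it increases along `dir`
  a0 <- which(dir != 0)[1]
  t_par <- co[, a0] * sign(dir[a0])
  # line identity: coordinates minus t_par * dir (constant along the line)
  key <- co - t_par %*% t(dir)
  ord <- order(key[, 1], key[, 2], key[, 3], t_par)
  co <- co[ord, , drop = FALSE]
  t_par <- t_par[ord]
  key <- key[ord, , drop = FALSE]
  lv <- levels[idx[ord]]
  n <- length(lv)
  same_line <- c(FALSE, key[-1, 1] == key[-n, 1] &
                        key[-1, 2] == key[-n, 2] &
                        key[-1, 3] == key[-n, 3])
  contiguous <- c(FALSE, t_par[-1] == t_par[-n] + 1L)
  same_level <- c(FALSE, lv[-1] == lv[-n])
  new_run <- !(same_line & contiguous & same_level)
  run_id <- cumsum(new_run)
  data.frame(level = lv[new_run],
             length = as.integer(tabulate(run_id, max(run_id))))
}

glrlm_features_one <- function(P, n_voxels) {
  G <- nrow(P); R <- ncol(P)
  Nr <- sum(P)
  if (Nr == 0) return(NULL)
  g <- row(P); r <- col(P)
  pg <- rowSums(P); pr <- colSums(P)
  c(
    glrlm_sre = sum(P / r^2) / Nr,
    glrlm_lre = sum(P * r^2) / Nr,
    glrlm_gln = sum(pg^2) / Nr,
    glrlm_rln = sum(pr^2) / Nr,
    glrlm_rp = Nr / n_voxels,
    glrlm_lglre = sum(P / g^2) / Nr,
    glrlm_hglre = sum(P * g^2) / Nr,
    glrlm_srlgle = sum(P / (g^2 * r^2)) / Nr,
    glrlm_srhgle = sum(P * g^2 / r^2) / Nr,
    glrlm_lrlgle = sum(P * r^2 / g^2) / Nr,
    glrlm_lrhgle = sum(P * g^2 * r^2) / Nr
  )
}

#' Grey-level run-length matrices and features (3D, 13 directions)
#'
#' Enumerates maximal runs of equal grey level along each of the 13
#' sign-unique 3D unit directions, restricted to the mask (runs break at the
#' mask boundary). Features are computed per direction from the G x Rmax
#' run-length matrix and then averaged over directions: short/long run
#' emphasis (SRE/LRE), grey-level and run-length non-uniformity (GLN/RLN),
#' run percentage (RP) and the low/high grey-level run emphases and their
#' short/long-run combinations.
#'
#' @param d_roi A [discretized_roi()].
#' @return List with `matrices` (one G x Rmax matrix per direction),
#'   `directions`, and `features` (named vector, prefix `glrlm_`, averaged
#'   over directions).
#' @export
glrlm <- function(d_roi) {
  stopifnot(inherits(d_roi, "discretized_roi"))
  G <- d_roi$n_levels
  dirs <- directions_13()
  n_vox <- sum(d_roi$mask)
  mats <- vector("list", nrow(dirs))
  feats <- NULL
  for (k in seq_len(nrow(dirs))) {
    runs <- glrlm_runs_direction(d_roi$levels, d_roi$mask, dirs[k, ])
    Rmax <- max(runs$length)
    P <- matrix(0, G, Rmax)
    tab <- table(factor(runs$level, levels = seq_len(G)),
                 factor(runs$length, levels = seq_len(Rmax)))
    P[] <- as.numeric(tab)
    mats[[k]] <- P
    f <- glrlm_features_one(P, n_vox)
    feats <- if (is.null(feats)) f else feats + f
  }
  feats <- feats / nrow(dirs)
  attr(feats, "family") <- rep("glrlm", length(feats))
  list(matrices = mats, directions = dirs, features = feats)
}
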