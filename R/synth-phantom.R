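#' Specify a 3D ROI phantom
#'
#' Defines a synthetic masked volume: an ellipsoidal ROI carved from a
#' rectangular grid, a constant base intensity, a configurable number of
#' Gaussian hyperintense blobs (emulating focal clustering of bright voxels)
#' and additive Gaussian noise. Phantoms give the texture pipeline inputs
#' with controllable smoothness and heterogeneity.
#'
#' @param shape Grid size per axis (length 3, each >= 3).
#' @param base_level Background intensity inside the ROI.
#' @param cluster_count Number of hyperintense blobs.
#' @param blob_sigma Blob width (voxels); larger values give smoother texture.
#' @param blob_amplitude Peak added intensity per blob.
#' @param noise_sd SD of additive voxel noise (>= 0).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(12L, 12L, 12L), base_level = 100,
                         cluster_count = 4L, blob_sigma = 1.5,
                         blob_amplitude = 25, noise_sd = 2,
                         spacing = c(1, 1, 1), seed = 1L) {
  if (length(shape) != 3L || any(shape < 3)) {
    stop_field("shape", "must be 3 integers >= 3")
  }
  check_scalar_num(cluster_count, "cluster_count", 0)
  check_scalar_num(blob_sigma, "blob_sigma", 0)
  check_scalar_num(noise_sd, "noise_sd", 0)
  if (2 * blob_sigma > max(shape)) {
    stop_field("blob_sigma", "blob larger than the grid")
  }
  structure(list(shape = as.integer(shape), base_level = base_level,
                 cluster_count = as.integer(cluster_count),
                 blob_sigma = blob_sigma, blob_amplitude = blob_amplitude,
                 noise_sd = noise_sd, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a 3D ROI phantom
#'
#' Builds the ellipsoidal mask, places `cluster_count` Gaussian blobs at
#' seeded random in-mask centres and adds voxel noise. Identical seeds give
#' identical volumes.
#'
#' @param spec A [phantom_spec()].
#' @param hemisphere Hemisphere label for the returned ROI.
#' @return An [roi_volume()].
#' @export
generate_phantom <- function(spec, hemisphere = NA_character_) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - (d[a] + 1) / 2) / (d[a] / 2))
  # ellipsoid inscribed in the grid
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- array(r2 <= 1, d)
  if (sum(mask) < 27L) mask <- array(TRUE, d)  # tiny grids: keep full mask
  vol <- array(spec$base_level, d)
  with_seed(spec$seed, {
    if (spec$cluster_count > 0L) {
      idx <- which(mask)
      centres <- arrayInd(sample(idx, spec$cluster_count, replace = TRUE), d)
      co <- lapply(1:3, function(a) seq_len(d[a]))
      for (b in seq_len(spec$cluster_count)) {
        dx2 <- outer(outer((co[[1]] - centres[b, 1])^2,
                           (co[[2]] - centres[b, 2])^2, `+`),
                     (co[[3]] - centres[b, 3])^2, `+`)
        vol <- vol + spec$blob_amplitude * exp(-dx2 / (2 * spec$blob_sigma^2))
      }
    }
    if (spec$noise_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(d), 0, spec$noise_sd), d)
    }
  })
  roi_volume(vol, mask, spacing = spec$spacing, hemisphere = hemisphere)
}
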