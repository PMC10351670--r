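#' Masked 3D region-of-interest volume
#'
#' Container for a 3D intensity grid with a binary mask, voxel spacing and a
#' hemisphere label. The mask must select at least 27 voxels (a 3x3x3
#' neighbourhood) so that neighbourhood-based texture is defined.
#'
#' @param intensities 3D numeric array.
#' @param mask 3D logical array of the same shape (or NULL for all-TRUE).
#' @param spacing Voxel spacing in mm per axis (length 3).
#' @param hemisphere `"left"`, `"right"` or `NA`.
#' @return An object of class `roi_volume`.
#' @export
roi_volume <- function(intensities, mask = NULL,
                       spacing = c(1, 1, 1), hemisphere = NA_character_) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop_field("intensities", "must be a 3D array")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(intensities))
  if (!identical(dim(mask), dim(intensities))) {
    stop_field("mask", "shape must match intensities")
  }
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop_field("mask", "must not contain NA")
  if (sum(mask) < 27L) stop_field("mask", "must select at least 27 voxels")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_field("spacing", "must be 3 positive numbers (mm)")
  }
  structure(list(intensities = intensities, mask = mask,
                 spacing = as.numeric(spacing), hemisphere = hemisphere),
            class = "roi_volume")
}

#' @export
print.roi_volume <- function(x, ...) {
  cat(sprintf("<roi_volume> %s grid, %d in-mask voxels, spacing %s mm, hemisphere %s\n",
              paste(dim(x$intensities), collapse = "x"), sum(x$mask),
              paste(signif(x$spacing, 3), collapse = "x"),
              x$hemisphere))
  invisible(x)
}

roi_values <- function(roi) roi$intensities[roi$mask]

#' Trim extreme in-mask intensities (mu +/- 3 sigma rule)
#'
#' Removes voxels whose intensity lies more than `k` SDs from the in-mask
#' mean from the mask (the classical trimming used to limit partial-volume
#' contamination at ROI boundaries). With zero in-mask SD nothing is removed
#' and a warning is issued.
#'
#' @param roi An [roi_volume()].
#' @param k SD multiplier (default 3).
#' @return The trimmed `roi_volume`; the number of removed voxels is in
#'   attribute `"n_trimmed"`.
#' @export
trim_extremes <- function(roi, k = 3) {
  stopifnot(inherits(roi, "roi_volume"))
  v <- roi_values(roi)
  if (length(v) < 2L) stop("need at least 2 in-mask voxels", call. = FALSE)
  mu <- mean(v); sg <- stats::sd(v)
  if (sg == 0) {
    warning("in-mask SD is zero; no voxels trimmed")
    attr(roi, "n_trimmed") <- 0L
    return(roi)
  }
  drop <- abs(roi$intensities - mu) > k * sg & roi$mask
  roi$mask <- roi$mask & !drop
  attr(roi, "n_trimmed") <- sum(drop)
  roi
}

#' Z-normalise in-mask intensities
#'
#' Centres and scales the in-mask intensities to mean 0, SD 1, normalising
#' intensity across participants before binning.
#'
#' @param roi An [roi_volume()].
#' @return The normalised `roi_volume`.
#' @export
znormalize <- function(roi) {
  stopifnot(inherits(roi, "roi_volume"))
  v <- roi_values(roi)
  sg <- stats::sd(v)
  if (!is.finite(sg) || sg == 0) stop("degenerate ROI: zero intensity SD", call. = FALSE)
  roi$intensities[roi$mask] <- (v - mean(v)) / sg
  roi
}

#' Discretised region of interest
#'
#' Integer bin indices 1..G inside the mask, NA outside.
#'
#' @param levels 3D integer array (NA outside mask).
#' @param mask 3D logical array.
#' @param n_levels Number of grey levels G.
#' @param spacing Voxel spacing (mm).
#' @return Object of class `discretized_roi`.
#' @export
discretized_roi <- function(levels, mask, n_levels, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(levels), dim(mask)))
  lv <- levels[mask]
  if (anyNA(lv) || any(lv < 1L) || any(lv > n_levels)) {
    stop_field("levels", "in-mask levels must lie in 1..n_levels")
  }
  structure(list(levels = levels, mask = mask, n_levels = as.integer(n_levels),
                 spacing = as.numeric(spacing)),
            class = "discretized_roi")
}

#' Discretise ROI intensities into equal-width bins
#'
#' Bins the in-mask intensity range \[min, max\] into `g_levels` equal-width
#' bins; the maximum value is assigned bin G.
#'
#' @param roi An [roi_volume()].
#' @param g_levels Number of bins (default 32).
#' @return A [discretized_roi()].
#' @export
discretize <- function(roi, g_levels = 32L) {
  stopifnot(inherits(roi, "roi_volume"))
  g_levels <- as.integer(g_levels)
  if (g_levels < 2L) stop_field("g_levels", "must be >= 2")
  v <- roi_values(roi)
  mn <- min(v); mx <- max(v)
  if (mx - mn <= 0) stop("degenerate ROI: zero intensity range", call. = FALSE)
  w <- (mx - mn) / g_levels
  lev <- array(NA_integer_, dim(roi$intensities))
  lev[roi$mask] <- pmin(g_levels, floor((v - mn) / w) + 1L)
  discretized_roi(lev, roi$mask, g_levels, roi$spacing)
}
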