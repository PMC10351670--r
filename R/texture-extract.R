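#' Extract all texture features from one hemisphere ROI
#'
#' Runs the full per-hemisphere pipeline: optional denoising hook, extreme
#' trimming (mu +/- 3 sigma), z-normalisation, equal-width discretisation,
#' then the first-order, GLCM and GLRLM families plus ROI volume (in-mask
#' voxel count times voxel volume, mm^3).
#'
#' @param roi An [roi_volume()].
#' @param n_bins Grey levels for discretisation (default 32).
#' @param trim_k SD multiplier for extreme trimming.
#' @param denoise Optional function `roi -> roi` applied before trimming
#'   (a hook for external denoisers); default identity.
#' @return Named numeric vector with attribute `family` mapping each feature
#'   to `first_order`, `glcm`, `glrlm` or `volume`.
#' @export
extract_features <- function(roi, n_bins = 32L, trim_k = 3, denoise = NULL) {
  stopifnot(inherits(roi, "roi_volume"))
  if (!is.null(denoise)) roi <- denoise(roi)
  # volume reflects the segmented ROI, before intensity-based trimming
  vol <- c(volume = sum(roi$mask) * prod(roi$spacing))
  roi <- trim_extremes(roi, k = trim_k)
  roi <- znormalize(roi)
  droi <- discretize(roi, g_levels = n_bins)
  fo <- first_order_features(roi, n_bins = n_bins)
  gl <- glcm_features(glcm(droi))
  rl <- glrlm(droi)$features
  out <- c(fo, gl, rl, vol)
  attr(out, "family") <- c(attr(fo, "family"), attr(gl, "family"),
                           attr(rl, "family"), "volume")
  out
}

#' Extract features for a subject: both hemispheres averaged
#'
#' Computes the full feature vector per hemisphere and averages element-wise
#' (volume included). If one hemisphere is missing, behaviour follows
#' `on_missing`: `"error"` (default) or `"passthrough"` (single-hemisphere
#' vector, flagged via attribute `single_hemisphere`).
#'
#' @param roi_left,roi_right [roi_volume()] objects (either may be NULL).
#' @param on_missing `"error"` or `"passthrough"`.
#' @inheritParams extract_features
#' @return Named numeric vector of hemisphere-averaged features.
#' @export
extract_all <- function(roi_left, roi_right, n_bins = 32L, trim_k = 3,
                        denoise = NULL, on_missing = c("error", "passthrough")) {
  on_missing <- match.arg(on_missing)
  have_l <- !is.null(roi_left); have_r <- !is.null(roi_right)
  if (!have_l && !have_r) stop("both hemispheres missing", call. = FALSE)
  if (!have_l || !have_r) {
    if (on_missing == "error") stop("one hemisphere missing", call. = FALSE)
    one <- extract_features(if (have_l) roi_left else roi_right,
                            n_bins = n_bins, trim_k = trim_k, denoise = denoise)
    attr(one, "single_hemisphere") <- TRUE
    return(one)
  }
  fl <- extract_features(roi_left, n_bins = n_bins, trim_k = trim_k,
                         denoise = denoise)
  fr <- extract_features(roi_right, n_bins = n_bins, trim_k = trim_k,
                         denoise = denoise)
  stopifnot(identical(names(fl), names(fr)))
  out <- (fl + fr) / 2
  attr(out, "family") <- attr(fl, "family")
  out
}
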