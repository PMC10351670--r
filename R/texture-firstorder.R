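#' First-order (histogram) texture features
#'
#' Statistics of the in-mask intensity distribution, ignoring spatial
#' arrangement. Skewness is the standardised third moment m3/m2^(3/2) and
#' kurtosis the standardised fourth moment m4/m2^2 (normal = 3), both with
#' population (1/n) moments. Energy is the sum of squared intensities;
#' entropy is Shannon entropy (bits) of the `n_bins` equal-width histogram
#' of in-mask values.
#'
#' @param roi An [roi_volume()].
#' @param n_bins Histogram bins used for the entropy feature.
#' @return Named numeric vector (prefix `fo_`) with attribute `family`.
#' @export
first_order_features <- function(roi, n_bins = 32L) {
  stopifnot(inherits(roi, "roi_volume"))
  v <- roi_values(roi)
  if (length(v) < 2L) stop("need at least 2 in-mask voxels", call. = FALSE)
  n <- length(v)
  m <- mean(v)
  cv <- v - m
  m2 <- mean(cv^2); m3 <- mean(cv^3); m4 <- mean(cv^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  rng <- range(v)
  if (diff(rng) > 0) {
    w <- diff(rng) / n_bins
    bins <- pmin(n_bins, floor((v - rng[1]) / w) + 1L)
    p <- tabulate(bins, n_bins) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  } else {
    ent <- 0
  }
  q <- stats::quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  out <- c(
    fo_mean = m, fo_median = stats::median(v), fo_sd = stats::sd(v),
    fo_variance = stats::var(v), fo_skewness = skew, fo_kurtosis = kurt,
    fo_min = rng[1], fo_max = rng[2], fo_range = diff(rng),
    fo_energy = sum(v^2), fo_entropy = ent,
    fo_p05 = q[1], fo_p25 = q[2], fo_p75 = q[3], fo_p95 = q[4]
  )
  attr(out, "family") <- rep("first_order", length(out))
  out
}
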