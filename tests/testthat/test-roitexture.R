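test_that("mu +/- 3 sigma trimming matches direct recomputation of the rule", {
  set.seed(42)
  a <- array(rnorm(1000), c(10, 10, 10))
  mu <- mean(a); sg <- sd(a)
  a[5, 5, 5] <- mu + 5 * sg  # planted extreme voxel
  roi <- roi_from_array(a)
  # oracle: recompute the rule directly on the updated values
  v <- as.vector(a)
  expected_removed <- sum(abs(v - mean(v)) > 3 * sd(v))
  tr <- trim_extremes(roi)
  expect_equal(attr(tr, "n_trimmed"), expected_removed)
  expect_false(tr$mask[5, 5, 5])

  # all values within the fence: mask unchanged
  b <- array(seq(-1, 1, length.out = 64), c(4, 4, 4))
  tr2 <- trim_extremes(roi_from_array(b))
  expect_equal(attr(tr2, "n_trimmed"), 0L)

  # constant ROI: sigma = 0 branch leaves the mask unchanged with a warning
  expect_warning(tr3 <- trim_extremes(roi_from_array(array(5, c(4, 4, 4)))),
                 "zero")
  expect_equal(sum(tr3$mask), 64)
})

test_that("z-normalisation yields exact moments and affine invariance", {
  set.seed(1)
  a <- array(rnorm(512, 50, 7), c(8, 8, 8))
  z <- znormalize(roi_from_array(a))
  v <- z$intensities[z$mask]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sd(v) - 1), 1e-10)
  # shift and scale invariance
  z2 <- znormalize(roi_from_array(a * 3.7 + 100))
  expect_equal(z2$intensities[z2$mask], v, tolerance = 1e-10)
  expect_error(znormalize(roi_from_array(array(2, c(4, 4, 4)))), "degenerate")
})

test_that("equal-width discretisation matches its closed form and histogram oracle", {
  # uniform values on [0, 1]: bin = ceil(32 v), clipped
  vals <- seq(0, 1, length.out = 64)
  a <- array(vals, c(4, 4, 4))
  d <- discretize(roi_from_array(a), 32)
  expected <- pmax(1L, pmin(32L, ceiling(32 * vals)))
  expect_equal(as.vector(d$levels), as.integer(expected))

  # two-level ROI occupies exactly bins 1 and 32
  b <- array(0, c(4, 4, 4)); b[1:32] <- 1e-6
  d2 <- discretize(roi_from_array(b), 32)
  expect_setequal(unique(as.vector(d2$levels)), c(1L, 32L))

  # random ROI: histogram equals an explicitly computed edge set
  set.seed(9)
  c3 <- array(rnorm(343), c(7, 7, 7))
  d3 <- discretize(roi_from_array(c3), 8)
  edges <- seq(min(c3), max(c3), length.out = 9)
  oracle_bins <- pmin(findInterval(as.vector(c3), edges,
                                   rightmost.closed = TRUE), 8L)
  expect_equal(tabulate(as.vector(d3$levels), 8), tabulate(oracle_bins, 8))
  expect_error(discretize(roi_from_array(array(1, c(3, 3, 3)))), "range")
})

test_that("first-order features match textbook-formula oracles", {
  set.seed(5)
  a <- array(rnorm(100, 3, 2), c(5, 5, 4))
  f <- first_order_features(roi_from_array(a))
  v <- as.vector(a)
  expect_equal(unname(f["fo_skewness"]), oracle_skew(v), tolerance = 1e-10)
  expect_equal(unname(f["fo_kurtosis"]), oracle_kurt(v), tolerance = 1e-10)
  expect_equal(unname(f["fo_mean"]), mean(v))
  expect_equal(unname(f["fo_energy"]), sum(v^2))
  expect_equal(unname(f["fo_p95"]), unname(quantile(v, 0.95)))

  zr <- znormalize(roi_from_array(a))
  fz <- first_order_features(zr)
  expect_lt(abs(fz["fo_mean"]), 1e-10)
  expect_equal(unname(fz["fo_sd"]), 1, tolerance = 1e-10)
})

test_that("GLCM equals brute-force pair enumeration on seeded small ROIs", {
  for (seed in 1:6) {
    G <- sample(4:8, 1)
    d <- random_droi(c(3, 3, 3) + seed %% 3, G, seed = seed,
                     mask_frac = if (seed %% 2) 1 else 0.8)
    if (sum(d$mask) < 8) next
    m <- glcm(d)
    o <- oracle_glcm(d$levels, d$mask, G)
    expect_equal(m, o, tolerance = 1e-12)
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_true(isSymmetric(m, tol = 1e-12))
  }
})

test_that("GLCM of a constant ROI is a point mass and features degenerate correctly", {
  lev <- array(3L, c(4, 4, 4))
  m <- glcm(droi_from_levels(lev, 5))
  expect_equal(m[3, 3], 1)
  expect_equal(sum(m), 1)
  f <- glcm_features(m)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_entropy"]), 0)
})

test_that("GLCM features match single-purpose formula oracles", {
  # uniform matrix over G = 4: entropy is exactly log2(16) = 4 bits
  u <- matrix(1 / 16, 4, 4)
  f <- glcm_features(u)
  expect_equal(unname(f["glcm_entropy"]), 4)
  # random normalised symmetric matrix
  set.seed(3)
  r <- matrix(runif(36), 6, 6); r <- r + t(r); r <- r / sum(r)
  fr <- glcm_features(r)
  expect_equal(unname(fr["glcm_contrast"]), oracle_glcm_contrast(r),
               tolerance = 1e-12)
  expect_equal(unname(fr["glcm_correlation"]), oracle_glcm_correlation(r),
               tolerance = 1e-12)
  expect_equal(unname(fr["glcm_asm"]), sum(r^2), tolerance = 1e-12)
  expect_equal(unname(fr["glcm_max_probability"]), max(r))
})

test_that("GLRLM run counts equal brute-force run enumeration", {
  # 1x1x8 constant line: a single run of length 8 along the axial direction
  lev <- array(2L, c(1, 1, 8))
  rl <- glrlm(droi_from_levels(lev, 3))
  ax <- which(apply(rl$directions, 1, function(d) all(d == c(0, 0, 1))))
  P <- rl$matrices[[ax]]
  expect_equal(sum(P), 1)
  expect_equal(P[2, 8], 1)

  # strictly alternating two-level line: all runs length 1, SRE = 1
  lev2 <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  rl2 <- glrlm(droi_from_levels(lev2, 2))
  xd <- which(apply(rl2$directions, 1, function(d) all(d == c(1, 0, 0))))
  expect_true(all(rl2$matrices[[xd]][, 1] == c(4, 4)))
  sre_x <- sum(rl2$matrices[[xd]][, 1]) / sum(rl2$matrices[[xd]])
  expect_equal(sre_x, 1)

  # seeded ROIs vs full enumeration in every direction
  for (seed in 1:5) {
    G <- sample(3:6, 1)
    d <- random_droi(c(4, 4, 4), G, seed = 100 + seed,
                     mask_frac = if (seed %% 2) 1 else 0.75)
    rl3 <- glrlm(d)
    for (k in seq_len(nrow(rl3$directions))) {
      o <- oracle_glrlm_matrix(d$levels, d$mask, rl3$directions[k, ], G)
      expect_equal(rl3$matrices[[k]], o, tolerance = 1e-12)
    }
  }
})

test_that("feature extraction is deterministic and affine-invariant", {
  ph <- generate_phantom(phantom_spec(shape = c(8, 8, 8), seed = 12))
  f1 <- extract_features(ph)
  f2 <- extract_features(ph)
  expect_identical(f1, f2)
  # affine rescaling of raw intensities leaves all features unchanged
  ph2 <- ph
  ph2$intensities <- ph2$intensities * 4.2 - 17
  f3 <- extract_features(ph2)
  expect_equal(f1, f3, tolerance = 1e-8)
})

test_that("hemisphere averaging behaves as element-wise mean with symmetry", {
  l <- generate_phantom(phantom_spec(shape = c(8, 8, 8), seed = 21),
                        hemisphere = "left")
  r <- generate_phantom(phantom_spec(shape = c(8, 8, 8), seed = 22),
                        hemisphere = "right")
  both <- extract_all(l, r)
  swapped <- extract_all(r, l)
  expect_equal(both, swapped)
  same <- extract_all(l, l)
  expect_equal(same, extract_features(l), ignore_attr = TRUE)
  expect_error(extract_all(l, NULL), "hemisphere")
  solo <- extract_all(l, NULL, on_missing = "passthrough")
  expect_true(attr(solo, "single_hemisphere"))
  # volume equals voxel count x voxel volume under anisotropic spacing
  la <- l; la$spacing <- c(0.5, 1, 2)
  fva <- extract_features(la)
  expect_equal(unname(fva["volume"]), sum(l$mask) * 0.5 * 1 * 2)
})

test_that("GLCM contrast decreases as phantom smoothing increases", {
  # dense blob coverage approximates a smoothed random field, so the blob
  # width directly sets the image smoothness scale
  for (seed in c(33, 34, 35)) {
    contrasts <- sapply(c(0.5, 1, 2), function(sg) {
      ph <- generate_phantom(phantom_spec(shape = c(14, 14, 14),
                                          cluster_count = 300,
                                          blob_amplitude = 5, blob_sigma = sg,
                                          noise_sd = 0, seed = seed))
      unname(extract_features(ph)["glcm_contrast"])
    })
    expect_true(all(diff(contrasts) < 0))
  }
})
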