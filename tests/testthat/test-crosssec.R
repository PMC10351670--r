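test_that("amyloid classification applies the CSF rule with borderline band", {
  expect_equal(as.character(classify_amyloid(900)), "positive")
  expect_equal(as.character(classify_amyloid(1000)), "excluded_borderline")
  expect_equal(as.character(classify_amyloid(1100)), "negative")
  expect_equal(as.character(classify_amyloid(NA, NA)), "unknown")
  # CSF takes precedence over PET
  expect_equal(as.character(classify_amyloid(900, centiloid = 0)), "positive")
  # PET fallback mirrors the configured threshold rule
  thr <- 20
  cl <- c(5, thr * 0.96, thr * 1.2)
  got <- classify_amyloid(rep(NA, 3), centiloid = cl, centiloid_threshold = thr)
  oracle <- ifelse(abs(cl - thr) <= 0.05 * thr, "excluded_borderline",
                   ifelse(cl > thr, "positive", "negative"))
  expect_equal(as.character(got), oracle)
  expect_error(classify_amyloid(-5), "csf_ab42")
})

test_that("mean +/- 1.5 IQR exclusion flags planted extremes only", {
  set.seed(3)
  v <- rnorm(200)
  expect_equal(sum(exclude_outliers(v)$flags),
               sum(abs(v - mean(v)) > 1.5 * IQR(v)))
  v2 <- c(v, 50)
  fl <- exclude_outliers(v2)$flags
  expect_true(fl[201])
  # symmetric data comfortably within the band: none flagged
  u <- seq(-1, 1, length.out = 100)
  expect_equal(sum(exclude_outliers(u)$flags), 0)
  # degenerate constant vector: IQR 0, only exact-mean values kept, so a
  # constant vector passes through and any deviating value collapses the band
  expect_equal(exclude_outliers(rep(2, 10))$values, rep(2, 10))
  w <- c(rep(2, 10), 3)  # mean leaves 2, so no value equals it
  expect_length(exclude_outliers(w)$values, 0)
})

test_that("Holm adjustment matches the step-down closed form", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(4)
  p <- runif(18)
  expect_equal(adjust_pvalues(p), oracle_holm(p))
  expect_true(all(adjust_pvalues(p) >= p))
  expect_true(all(diff(adjust_pvalues(sort(p))) >= 0))
  # Benjamini-Hochberg available by configuration
  expect_equal(adjust_pvalues(p, method = "BH"), p.adjust(p, "BH"))
})

test_that("effect sizes reduce to their closed forms", {
  # two equal-n groups, means 0 and 1, pooled SD 1: d = 1, f = d/2
  set.seed(5)
  x <- rnorm(4000); x <- (x - mean(x)) / sd(x)
  y <- x + 1
  expect_equal(cohens_d(y, x), 1, tolerance = 1e-12)
  tab <- make_baseline_table(n = 600, n_groups = 4, seed = 6)
  fit <- fit_group_model(tab, "y")
  # f matches the direct between/within variance-ratio formula
  gm <- fit$group_means; ns <- fit$group_ns
  mb <- sum(ns * gm) / sum(ns)
  f_direct <- sqrt(sum(ns * (gm - mb)^2) / sum(ns)) / fit$sigma
  expect_equal(fit$cohens_f, f_direct, tolerance = 1e-12)
})

test_that("group model reports site variance and validates its design", {
  # zero generated site variance: estimated site SD near 0 (averaged over
  # seeds since single-fit variance estimates sit at or near the boundary)
  site_sds <- vapply(7:11, function(sd) {
    fit_group_model(make_baseline_table(n = 300, site_sd = 0, seed = sd),
                    "y")$site_sd
  }, numeric(1))
  expect_lt(mean(site_sds), 0.06)

  tab <- make_baseline_table(n = 300, site_sd = 0, seed = 7)
  fit <- fit_group_model(tab, "y")
  expect_setequal(fit$anova$term,
                  c("group_bl", "age_bl", "sex", "education", "icv"))
  expect_true(all(fit$anova$p >= 0 & fit$anova$p <= 1))

  tab1 <- tab; tab1$site <- "site01"
  expect_warning(fit1 <- fit_group_model(tab1, "y"), "site")
  expect_equal(fit1$site_sd, 0)

  tab2 <- tab; tab2$education <- tab2$age_bl  # aliased covariate
  expect_error(fit_group_model(tab2, "y"), "aliased")
  expect_error(fit_group_model(tab[tab$group_bl == "CU-Ab-", ], "y"),
               "2 groups")
})

test_that("pairwise contrasts recover planted standardised differences", {
  tab <- make_baseline_table(n = 1200, group_effects = c(0, 0, 1, 0), seed = 8)
  pc <- pairwise_contrasts(tab, "y")
  d_mci <- pc$d[pc$comparison == "CU-Ab- vs MCI-Ab+"]
  expect_lt(abs(d_mci - 1), 0.2)
  d_null <- pc$d[pc$comparison == "CU-Ab- vs CU-Ab+"]
  expect_lt(abs(d_null), 0.2)
  expect_error(pairwise_contrasts(tab, "y", others = "CU-Ab-"), "itself")
})

test_that("planted group shift is recovered without bias over replicates", {
  # mean estimated contrast within 0.05 of the generating 0.5 SD shift
  reps <- 60
  est <- vapply(seq_len(reps), function(r) {
    tab <- make_baseline_table(n = 300, group_effects = c(0, 0.5, 0, 0),
                               seed = 1000 + r)
    fit <- fit_group_model(tab[tab$group_bl %in% c("CU-Ab-", "CU-Ab+"), ], "y")
    unname(fit$group_means["CU-Ab+"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})
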