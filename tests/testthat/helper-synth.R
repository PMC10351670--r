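# Shared fixture builders (all generated in code; nothing stored on disk).

# ROI wrapping a full-mask array
roi_from_array <- function(a, spacing = c(1, 1, 1)) {
  roi_volume(a, array(TRUE, dim(a)), spacing = spacing)
}

# discretised ROI straight from a level array (bypasses the intensity
# pipeline; used for tiny run-length and co-occurrence fixtures)
droi_from_levels <- function(lev, G, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(lev))
  lev[!mask] <- NA_integer_
  discretized_roi(lev, mask, G)
}

random_droi <- function(shape, G, seed, mask_frac = 1) {
  set.seed(seed)
  lev <- array(sample.int(G, prod(shape), replace = TRUE), shape)
  mask <- array(TRUE, shape)
  if (mask_frac < 1) {
    mask <- array(runif(prod(shape)) < mask_frac, shape)
  }
  lev[!mask] <- NA_integer_
  discretized_roi(lev, mask, G)
}

# baseline-style table for the cross-sectional models
make_baseline_table <- function(n = 400, n_groups = 4, n_sites = 8,
                                group_effects = rep(0, n_groups),
                                site_sd = 0.3, seed = 1) {
  set.seed(seed)
  groups <- c("CU-Ab-", "CU-Ab+", "MCI-Ab+", "ADD-Ab+")[seq_len(n_groups)]
  g <- sample(groups, n, replace = TRUE)
  site <- sample(sprintf("site%02d", seq_len(n_sites)), n, replace = TRUE)
  site_eff <- rnorm(n_sites, 0, site_sd)
  age <- rnorm(n, 73, 7)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  edu <- round(rnorm(n, 16, 2.5))
  icv <- rnorm(n, 1.5e6, 1.5e5)
  y <- group_effects[match(g, groups)] + 0.02 * (age - 73) +
    site_eff[as.integer(sub("site", "", site))] + rnorm(n)
  data.frame(group_bl = g, age_bl = age, sex = sex, education = edu,
             icv = icv, site = site, y = y, stringsAsFactors = FALSE)
}

# staged trajectory data from a known spline + random intercepts
make_staged_data <- function(n_subj = 300, visits = 4, curve, tau = 1,
                             sigma = 1, t_range = c(-8, 12), seed = 1,
                             age_fun = NULL) {
  set.seed(seed)
  id <- sprintf("T%04d", seq_len(n_subj))
  t0 <- runif(n_subj, t_range[1], t_range[2] - 2)
  x <- rnorm(n_subj, 0, tau)
  rows <- lapply(seq_len(n_subj), function(i) {
    tt <- t0[i] + seq(0, 2, length.out = visits)
    data.frame(subject_id = id[i], disease_time = tt,
               visit_years = seq(0, 2, length.out = visits),
               value = curve(tt) + x[i] + rnorm(visits, 0, sigma),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# trajectory_fit built directly from chosen spline coefficients, for exact
# closed-form curve checks
manual_fit <- function(beta, knots, boundary, sigma2 = 1, tau2 = 0.5) {
  structure(list(outcome = "manual", dof = length(beta) - 1L, beta = beta,
                 knots = knots, boundary = boundary, tau2 = tau2,
                 sigma2 = sigma2, support = boundary,
                 bic_table = NULL, n = NA_integer_),
            class = "trajectory_fit")
}

# staged data over both timescales with a chosen generating form
make_dual_data <- function(seed, n_subj = 400,
                           effect = c("additive", "interaction", "constant")) {
  effect <- match.arg(effect)
  set.seed(seed)
  id <- sprintf("D%04d", seq_len(n_subj))
  age0 <- runif(n_subj, 60, 85)
  t0 <- runif(n_subj, -6, 10)
  x <- rnorm(n_subj, 0, 1)
  rows <- lapply(seq_len(n_subj), function(i) {
    vy <- 0:3
    dt <- t0[i] + vy
    at0 <- age0[i] - t0[i]
    mu <- switch(effect,
      additive = 0.8 * dt + 0.15 * (at0 - 72),
      interaction = 0.5 * dt + 0.1 * (at0 - 72) + 0.06 * dt * (at0 - 72),
      constant = 0)
    data.frame(subject_id = id[i], visit_years = vy, disease_time = dt,
               age_bl = age0[i], value = mu + x[i] + rnorm(4, 0, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# outcome family with residual variances (1, 4, 9, 16) and unbounded
# sigmoidal monotone means, for variance-recovery checks
recovery_outcome_params <- function() {
  tms <- c(-12, -6, 0, 6, 12, 16)
  list(
    out1 = list(times = tms, values = c(0, 6, 14, 26, 36, 40),
                floor = -Inf, ceiling = Inf, intercept_sd = 2, resid_sd = 1),
    out2 = list(times = tms, values = c(0, 5, 18, 42, 55, 60),
                floor = -Inf, ceiling = Inf, intercept_sd = 2, resid_sd = 2),
    out3 = list(times = tms, values = c(0, 10, 25, 55, 72, 80),
                floor = -Inf, ceiling = Inf, intercept_sd = 2, resid_sd = 3),
    out4 = list(times = tms, values = c(0, 8, 30, 70, 92, 100),
                floor = -Inf, ceiling = Inf, intercept_sd = 2, resid_sd = 4))
}

# prediction frame with optional planted standardised texture effect
make_pred_frame <- function(n, seed, tx_effect = 0, resid_sd = 3) {
  set.seed(seed)
  fr <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                   score_bl = rnorm(n, 20, 6), age_bl = rnorm(n, 73, 7),
                   sex = sample(c("F", "M"), n, TRUE),
                   education = round(rnorm(n, 16, 2.5)),
                   icv = rnorm(n, 1.5e6, 1.5e5), hv = rnorm(n),
                   stringsAsFactors = FALSE)
  for (i in 1:5) fr[[paste0("txpc", i)]] <- rnorm(n)
  fr$y <- fr$score_bl + 0.5 * fr$hv + tx_effect * resid_sd * fr$txpc1 +
    rnorm(n, 0, resid_sd)
  fr
}
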