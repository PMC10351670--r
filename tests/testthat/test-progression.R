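# A moderate synthetic cohort fitted once and reused across blocks.
prog_cohort <- generate_cohort(cohort_spec(n_per_group = 25, shift_sd = 3,
                                           seed = 202))
prog_fit <- suppressWarnings(
  fit_progression(prog_cohort$data, c("adas13", "cdrsb", "mmse", "centiloid"),
                  max_iter = 150))

# independent oracle for a subject's marginal log-likelihood: explicit
# covariance matrices, generic determinant/solve
oracle_subject_ll <- function(fit, obs, m_i, s) {
  ll <- dnorm(s, 0, sqrt(fit$shift_var), log = TRUE)
  for (k in names(obs)) {
    o <- obs[[k]]
    if (length(o$y) == 0) next
    th <- fit$theta[[k]]
    mu <- as.numeric(cbind(1, splines::ns(o$t + m_i + s, knots = th$knots,
                                          Boundary.knots = th$boundary)) %*%
                       th$beta)
    n <- length(o$y)
    V <- diag(fit$resid_vars[[k]], n) +
      matrix(fit$intercept_vars[[k]], n, n)
    r <- o$y - mu
    ll <- ll - 0.5 * (n * log(2 * pi) +
                        determinant(V, logarithm = TRUE)$modulus +
                        sum(r * solve(V, r)))
  }
  as.numeric(ll)
}

test_that("zero-shift zero-noise limit returns disease time equal to visit time", {
  set.seed(30)
  n <- 60
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- 0:4
    data.frame(subject_id = sprintf("L%03d", i), visit_years = tt,
               group_bl = "CU-Ab-", age_bl = 73, sex = "F", education = 16,
               icv = 1.5e6, site = "site01",
               outcome = "lin", value = 2 * tt + rnorm(5, 0, 0.01))
  }))
  expect_warning(fit <- fit_progression(rows, "lin", reference = "CU-Ab-",
                                        max_iter = 40),
                 "weakly identified")
  staged <- predict_disease_time(fit, rows)
  expect_lt(max(abs(staged$disease_time - staged$visit_years)), 0.1)
})

test_that("latent shifts and subject orderings are recovered on a synthetic cohort", {
  tr <- prog_cohort$truth$subjects
  j <- match(prog_fit$shifts$subject_id, tr$subject_id)
  expect_gt(cor(prog_fit$shifts$shift_total, tr$shift_total[j]), 0.85)
  # group offsets ordered along the generated continuum
  off <- prog_fit$group_offsets
  expect_true(off["CU-Ab+"] < off["MCI-Ab+"] &&
                off["MCI-Ab+"] < off["ADD-Ab+"])
  expect_equal(unname(off["CU-Ab-"]), 0)
  # penalised log-likelihood is non-decreasing once knots are frozen
  frozen <- prog_fit$loglik_trace[-seq_len(11)]
  expect_true(all(diff(frozen) > -1e-6))
})

test_that("MAP staging agrees with a dense grid search of the posterior", {
  fit <- prog_fit
  ids <- prog_fit$shifts$subject_id[c(5, 40, 80)]
  for (id in ids) {
    rows <- prog_cohort$data[prog_cohort$data$subject_id == id &
                               prog_cohort$data$outcome %in% fit$outcomes, ]
    staged <- predict_disease_time(fit, rows)
    s_hat <- attr(staged, "shifts")$shift_random[1]
    m_i <- attr(staged, "shifts")$shift_fixed[1]
    obs <- lapply(fit$outcomes, function(k) {
      sel <- rows$outcome == k & !is.na(rows$value)
      list(t = rows$visit_years[sel], y = rows$value[sel])
    })
    names(obs) <- fit$outcomes
    sgrid <- seq(-4.5 * sqrt(fit$shift_var), 4.5 * sqrt(fit$shift_var),
                 by = 0.01)
    ll <- vapply(sgrid, function(s) oracle_subject_ll(fit, obs, m_i, s),
                 numeric(1))
    expect_lt(abs(s_hat - sgrid[which.max(ll)]), 0.011)
  }
})

test_that("a subject lying exactly on its group mean curve gets shift about zero", {
  fit <- prog_fit
  m_ref <- 0  # reference-group subject at the cohort mean age
  tt <- 0:3
  rows <- do.call(rbind, lapply(fit$outcomes, function(k) {
    data.frame(subject_id = "EXACT", visit_years = tt, group_bl = "CU-Ab-",
               age_bl = fit$age_center, sex = "F", education = 16,
               icv = 1.5e6, site = "site01", outcome = k,
               value = eval_trajectory(fit, k, tt + m_ref))
  }))
  staged <- predict_disease_time(fit, rows)
  expect_lt(abs(attr(staged, "shifts")$shift_random[1]), 0.05)
})

test_that("duplicating noise-free visits moves the MAP shift toward the truth", {
  # with observations exactly on the shifted mean curves the likelihood
  # mode is the true shift, so doubling the data weight must pull the
  # posterior mode from its shrunken value toward the truth
  fit <- prog_fit
  set.seed(31)
  s_true <- rnorm(60, 0, sqrt(fit$shift_var))
  for (r in seq_along(s_true)) {
    tt <- 0:2
    rows <- do.call(rbind, lapply(fit$outcomes, function(k) {
      data.frame(subject_id = "DUP", visit_years = tt, group_bl = "CU-Ab-",
                 age_bl = fit$age_center, sex = "F", education = 16,
                 icv = 1.5e6, site = "site01", outcome = k,
                 value = eval_trajectory(fit, k, tt + s_true[r]))
    }))
    s1 <- attr(predict_disease_time(fit, rows), "shifts")$shift_random[1]
    s2 <- attr(predict_disease_time(fit, rbind(rows, rows)),
               "shifts")$shift_random[1]
    expect_lte(abs(s2 - s_true[r]), abs(s1 - s_true[r]) + 0.02)
    expect_gte(abs(s2), abs(s1) - 0.02)  # shrinkage toward 0 weakens
  }
})

test_that("fitted mean curves are monotone where curves are identifiable", {
  # at noise levels where every curve segment is identifiable relative to
  # the residual SD, the fitted trajectories reproduce the generating
  # monotonicity (small boundary wiggle tolerated); at higher noise the
  # alternating alignment can carve interior wiggle, a documented limit
  op <- default_outcome_params()
  for (k in names(op)) op[[k]]$resid_sd <- op[[k]]$resid_sd * 0.5
  co <- generate_cohort(cohort_spec(n_per_group = 60, shift_sd = 3,
                                    outcome_params = op, seed = 203))
  fit <- suppressWarnings(fit_progression(
    co$data, c("adas13", "cdrsb", "mmse", "centiloid"), max_iter = 150))
  staged <- predict_disease_time(fit, co$data)
  rng <- quantile(staged$disease_time, c(0.05, 0.95))
  tgrid <- seq(rng[1], rng[2], length.out = 100)
  for (k in fit$outcomes) {
    v <- eval_trajectory(fit, k, tgrid)
    d <- diff(v) * if (k == "mmse") -1 else 1
    rel_reversal <- -sum(pmin(d, 0)) / abs(max(v) - min(v))
    expect_lt(rel_reversal, 0.10)
  }
})

test_that("time-zero anchoring finds a constructed crossing and handles ties", {
  set.seed(32)
  tt <- runif(600, -5, 10)
  healthy <- rnorm(500, 1400, 100)
  thr <- quantile(healthy, 0.05, names = FALSE)
  slope <- 50
  t_star <- (1400 - thr) / slope
  staged <- data.frame(disease_time = tt, value = 1400 - slope * tt)
  anc <- anchor_time_zero(staged, healthy)
  expect_lt(abs(anc$time_zero - t_star), 0.15)
  expect_equal(anc$offset, -anc$time_zero)

  # threshold never crossed
  flat <- data.frame(disease_time = tt, value = rep(1500, length(tt)))
  expect_error(anchor_time_zero(flat, healthy), "cannot anchor")

  # flat median exactly at threshold: first-index convention
  at_thr <- data.frame(disease_time = tt, value = rep(thr, length(tt)))
  anc2 <- anchor_time_zero(at_thr, healthy)
  expect_equal(anc2$time_zero, min(tt))

  # applying the anchor shifts predicted disease times by the offset
  fit2 <- apply_anchor(prog_fit, anc$offset)
  staged0 <- predict_disease_time(prog_fit, prog_cohort$data)
  staged1 <- predict_disease_time(fit2, prog_cohort$data)
  expect_equal(staged1$disease_time, staged0$disease_time + anc$offset,
               tolerance = 1e-6)
})

test_that("timeline estimates are invariant to a constant shift of all groups", {
  op <- default_outcome_params()
  # widen control ranges so a global translation never hits curve clamps
  for (k in names(op)) {
    p <- op[[k]]
    sl_lo <- (p$values[2] - p$values[1]) / (p$times[2] - p$times[1])
    sl_hi <- (p$values[7] - p$values[6]) / (p$times[7] - p$times[6])
    op[[k]]$times <- c(-30, p$times, 34)
    op[[k]]$values <- c(p$values[1] - 18 * sl_lo, p$values,
                        p$values[7] + 18 * sl_hi)
    op[[k]]$floor <- -Inf; op[[k]]$ceiling <- Inf
  }
  base_means <- c("CU-Ab-" = -6, "CU-Ab+" = 0, "MCI-Ab+" = 5.5,
                  "ADD-Ab+" = 10)
  fits <- lapply(c(0, 3), function(cshift) {
    co <- generate_cohort(cohort_spec(n_per_group = 20, shift_sd = 3,
                                      shift_mean_by_group = base_means + cshift,
                                      outcome_params = op, seed = 77))
    suppressWarnings(fit_progression(
      co$data, c("adas13", "cdrsb", "mmse", "centiloid"), max_iter = 120))
  })
  # identical seeds give identical random draws, so the two cohorts differ
  # only by the 3-year translation; anchored offsets must agree
  for (g in c("CU-Ab+", "MCI-Ab+", "ADD-Ab+")) {
    expect_lt(abs(fits[[1]]$group_offsets[g] - fits[[2]]$group_offsets[g]), 1.0)
  }
  expect_gt(cor(fits[[1]]$shifts$shift_total, fits[[2]]$shifts$shift_total),
            0.98)
})

test_that("progression fit is reproducible and serialises to JSON", {
  expect_equal(prog_fit$shifts,
               suppressWarnings(fit_progression(
                 prog_cohort$data, c("adas13", "cdrsb", "mmse", "centiloid"),
                 max_iter = 150))$shifts)
  path <- tempfile(fileext = ".json")
  write_progression_json(prog_fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$shift_var, prog_fit$shift_var, tolerance = 1e-12)
  expect_equal(back$theta$adas13$beta, prog_fit$theta$adas13$beta,
               tolerance = 1e-12)
})
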