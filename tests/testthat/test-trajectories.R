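test_that("disease-time trimming drops the extreme quantiles symmetrically", {
  curve <- function(t) t
  st <- make_staged_data(n_subj = 100, visits = 4, curve = curve, seed = 2)
  tf <- fit_trajectory(st, "lin")
  q <- quantile(st$disease_time, c(0.025, 0.975))
  n_expected <- sum(st$disease_time >= q[1] & st$disease_time <= q[2])
  expect_equal(tf$n, n_expected)
  expect_gte(tf$support[1], q[1])
  expect_lte(tf$support[2], q[2])
  # per-tail option trims more
  tf2 <- fit_trajectory(st, "lin", trim_per_tail = TRUE)
  expect_lt(tf2$n, tf$n)
  expect_error(fit_trajectory(st[1:40, ], "lin"), "50 observations")
})

test_that("BIC selects the generating spline complexity", {
  # data generated from a 4-DoF natural spline: 4 selected most of the time
  kn <- list(knots = c(-2, 2, 6), boundary = c(-7, 11))
  set.seed(40)
  beta_true <- c(5, 4, -3, 6, 2)
  gen_curve <- function(t) {
    as.numeric(cbind(1, splines::ns(t, knots = kn$knots,
                                    Boundary.knots = kn$boundary)) %*% beta_true)
  }
  hits <- vapply(1:10, function(sd) {
    st <- make_staged_data(n_subj = 500, visits = 4, curve = gen_curve,
                           tau = 1, sigma = 1, seed = 400 + sd)
    fit_trajectory(st, "spl")$dof
  }, numeric(1))
  expect_gte(mean(hits == 4), 0.7)

  # pure noise: the minimum DoF is the modal choice
  noise_dofs <- vapply(1:10, function(sd) {
    st <- make_staged_data(n_subj = 200, visits = 4,
                           curve = function(t) 0 * t, tau = 0.5, sigma = 1,
                           seed = 500 + sd)
    fit_trajectory(st, "noise")$dof
  }, numeric(1))
  expect_equal(as.integer(names(which.max(table(noise_dofs)))), 3L)
})

test_that("zero generated intercept variance is recovered as near-zero tau2", {
  st <- make_staged_data(n_subj = 400, visits = 4,
                         curve = function(t) 0.5 * t, tau = 0, sigma = 2,
                         seed = 41)
  tf <- fit_trajectory(st, "flat")
  expect_lt(tf$tau2, 0.05 * tf$sigma2)
})

test_that("abnormality curve hits 0, 1 and the midpoint by construction", {
  kn <- list(knots = c(2, 5), boundary = c(0, 10))
  sc <- abnormality_scale(c(rep(1, 50), rnorm(50, 1, 0.2)),
                          direction = "increasing")
  # constant trajectory at the healthy median
  f0 <- manual_fit(c(sc$q50, 0, 0, 0), kn$knots, kn$boundary)
  expect_equal(abnormality_curve(f0, sc, seq(0, 10, 1)), rep(0, 11))
  # constant at the 95% quantile
  f1 <- manual_fit(c(sc$q95, 0, 0, 0), kn$knots, kn$boundary)
  expect_equal(abnormality_curve(f1, sc, seq(0, 10, 1)), rep(1, 11))
  # linear from q50 at t=0 to q95 at t=10: abnormality 0.5 at the midpoint
  tg <- seq(0, 10, length.out = 201)
  B <- cbind(1, splines::ns(tg, knots = kn$knots, Boundary.knots = kn$boundary))
  target <- sc$q50 + (sc$q95 - sc$q50) * tg / 10
  beta_lin <- solve(crossprod(B), crossprod(B, target))
  flin <- manual_fit(as.numeric(beta_lin), kn$knots, kn$boundary)
  expect_equal(abnormality_curve(flin, sc, 5), 0.5, tolerance = 1e-8)
  # affine equivariance: rescaling the outcome leaves the curve unchanged
  sc2 <- abnormality_scale(7 * c(rep(1, 50), rnorm(50, 1, 0.2))[1:100] + 3)
  f2 <- manual_fit(as.numeric(beta_lin) * 7 + c(3, 0, 0, 0),
                   kn$knots, kn$boundary)
  sc2 <- structure(list(q50 = sc$q50 * 7 + 3, q95 = sc$q95 * 7 + 3,
                        direction = "increasing"), class = "abnormality_scale")
  expect_equal(abnormality_curve(f2, sc2, tg),
               abnormality_curve(flin, sc, tg), tolerance = 1e-8)
})

test_that("sensitivity curve matches closed forms and a numerical derivative", {
  kn <- list(knots = c(2, 5), boundary = c(0, 10))
  # constant trajectory: sensitivity identically 0
  f0 <- manual_fit(c(4, 0, 0, 0), kn$knots, kn$boundary, sigma2 = 2)
  expect_equal(sensitivity_curve(f0, seq(0, 10, 0.5)), rep(0, 21))
  # theta(t) = sigma-hat * t: sensitivity identically 1 per year
  tg <- seq(0, 10, length.out = 400)
  B <- cbind(1, splines::ns(tg, knots = kn$knots, Boundary.knots = kn$boundary))
  sigma2 <- 2.89
  beta_lin <- solve(crossprod(B), crossprod(B, sqrt(sigma2) * tg))
  flin <- manual_fit(as.numeric(beta_lin), kn$knots, kn$boundary,
                     sigma2 = sigma2)
  expect_equal(sensitivity_curve(flin, seq(0.5, 9.5, 0.5)),
               rep(1, 19), tolerance = 1e-6)
  # arbitrary spline: agreement with an independent central difference
  set.seed(42)
  fr <- manual_fit(rnorm(4, 0, 3), kn$knots, kn$boundary, sigma2 = 1.7)
  tt <- seq(1, 9, 0.25)
  h <- 1e-5
  num <- (predict_trajectory(fr, tt + h) - predict_trajectory(fr, tt - h)) /
    (2 * h) / sqrt(fr$sigma2)
  expect_equal(sensitivity_curve(fr, tt), num, tolerance = 1e-6)
  # invariant to adding a constant to the outcome
  fshift <- fr; fshift$beta[1] <- fshift$beta[1] + 11
  expect_equal(sensitivity_curve(fshift, tt), sensitivity_curve(fr, tt))
})

test_that("dual-timescale selection recovers generating forms", {
  forms <- vapply(1:5, function(sd) {
    fit_dual_timescale(make_dual_data(600 + sd, effect = "additive"))$form
  }, character(1))
  expect_gte(mean(forms == "additive"), 0.8)
  forms_i <- vapply(1:5, function(sd) {
    fit_dual_timescale(make_dual_data(700 + sd, effect = "interaction"))$form
  }, character(1))
  expect_gte(mean(forms_i == "interaction"), 0.8)
  forms_c <- vapply(1:5, function(sd) {
    fit_dual_timescale(make_dual_data(800 + sd, effect = "constant", n_subj = 150))$form
  }, character(1))
  expect_gte(mean(forms_c == "null"), 0.8)
  # the reported BIC is the minimum over the candidate table
  df <- fit_dual_timescale(make_dual_data(601, effect = "additive"))
  expect_equal(df$bic, min(df$candidates$bic))
})
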