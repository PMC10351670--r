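# Outcome trajectories over predicted disease time.
#
# v_ij = theta(t~_ij) + x_i + eps_ij, theta a natural cubic spline, x_i a
# zero-mean Gaussian subject random intercept (variance tau2), eps_ij
# Gaussian residual (variance sigma2). Spline degrees of freedom are chosen
# by BIC under ML over a candidate range; the selected model is refitted by
# REML for final variance estimates.

trim_disease_time <- function(t, trim = 0.05, per_tail = FALSE) {
  probs <- if (per_tail) c(trim, 1 - trim) else c(trim / 2, 1 - trim / 2)
  q <- stats::quantile(t, probs, names = FALSE)
  t >= q[1] & t <= q[2]
}

#' Fit an outcome trajectory over disease time
#'
#' Trims the extreme quantiles of disease time (5% total by default, split
#' symmetrically across tails), selects spline degrees of freedom by BIC
#' among `dof_range` under maximum likelihood, and refits the selected
#' model by REML.
#'
#' @param staged Data frame with columns `disease_time`, `value`,
#'   `subject_id` (rows of one outcome).
#' @param outcome Label stored with the fit.
#' @param dof_range Candidate spline degrees of freedom (default 3:6).
#' @param trim Total fraction of extreme disease-time quantiles excluded.
#' @param trim_per_tail If TRUE, `trim` is applied per tail instead.
#' @return Object of class `trajectory_fit`: `dof`, `beta`, `knots`,
#'   `boundary`, `tau2`, `sigma2` (REML), `support` (trimmed disease-time
#'   range), `bic_table`, `n`.
#' @export
fit_trajectory <- function(staged, outcome = "outcome", dof_range = 3:6,
                           trim = 0.05, trim_per_tail = FALSE) {
  ok <- !is.na(staged$value) & !is.na(staged$disease_time)
  d <- staged[ok, , drop = FALSE]
  keep <- trim_disease_time(d$disease_time, trim, trim_per_tail)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 50L) stop("fewer than 50 observations after trimming",
                          call. = FALSE)
  cand <- list()
  for (dof in dof_range) {
    kn <- make_knots(d$disease_time, dof)
    B <- cbind(1, ns_basis(d$disease_time, kn$knots, kn$boundary))
    f <- tryCatch(fit_ri_lmm(B, d$value, d$subject_id, reml = FALSE),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("trajectory candidate dof=%d skipped (singular fit)", dof))
      next
    }
    cand[[as.character(dof)]] <- list(dof = dof, kn = kn, bic = bic_ri_lmm(f))
  }
  if (length(cand) == 0L) stop("all spline candidates failed", call. = FALSE)
  bics <- vapply(cand, `[[`, numeric(1), "bic")
  sel <- cand[[which.min(bics)]]
  B <- cbind(1, ns_basis(d$disease_time, sel$kn$knots, sel$kn$boundary))
  f <- fit_ri_lmm(B, d$value, d$subject_id, reml = TRUE)
  structure(list(outcome = outcome, dof = sel$dof, beta = f$beta,
                 knots = sel$kn$knots, boundary = sel$kn$boundary,
                 tau2 = f$tau2, sigma2 = f$sigma2,
                 support = range(d$disease_time),
                 bic_table = data.frame(dof = as.integer(names(bics)),
                                        bic = unname(bics)),
                 n = nrow(d)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s: %d-DoF spline over disease time [%.1f, %.1f] y; tau2 %.3g, sigma2 %.3g (REML)\n",
              x$outcome, x$dof, x$support[1], x$support[2], x$tau2, x$sigma2))
  invisible(x)
}

#' Evaluate a fitted trajectory
#'
#' @param fit A [fit_trajectory()] fit.
#' @param t Disease times.
#' @return theta-hat(t).
#' @export
predict_trajectory <- function(fit, t) {
  as.numeric(cbind(1, ns_basis(t, fit$knots, fit$boundary)) %*% fit$beta)
}

#' Healthy-reference abnormality scale
#'
#' Records the median and the 95% quantile in the direction of abnormality
#' of a healthy reference sample: for outcomes where abnormality means
#' higher values the 0.95 quantile, where it means lower values the 0.05
#' quantile.
#'
#' @param healthy_values Reference observations.
#' @param direction `"increasing"` (higher = abnormal) or `"decreasing"`.
#' @return Object of class `abnormality_scale` with `q50`, `q95`,
#'   `direction`.
#' @export
abnormality_scale <- function(healthy_values,
                              direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  q50 <- stats::median(healthy_values)
  q95 <- stats::quantile(healthy_values,
                         if (direction == "increasing") 0.95 else 0.05,
                         names = FALSE)
  if (q95 == q50) stop("degenerate reference: q95 equals median", call. = FALSE)
  structure(list(q50 = q50, q95 = q95, direction = direction),
            class = "abnormality_scale")
}

#' Abnormality curve of a trajectory
#'
#' Re-expresses the estimated trajectory in units of (healthy 95% quantile
#' minus healthy median): 0 where theta-hat equals the healthy median, 1
#' where it equals the healthy 95% quantile in the direction of
#' abnormality.
#'
#' @param fit A [fit_trajectory()] fit.
#' @param scale An [abnormality_scale()].
#' @param t Disease-time grid.
#' @return Numeric vector of abnormality values.
#' @export
abnormality_curve <- function(fit, scale, t) {
  stopifnot(inherits(scale, "abnormality_scale"))
  (predict_trajectory(fit, t) - scale$q50) / (scale$q95 - scale$q50)
}

# derivative of the fitted spline by Richardson-extrapolated central
# differences (exact to O(h^4); h = 1e-3 y)
trajectory_derivative <- function(fit, t, h = 1e-3) {
  (8 * (predict_trajectory(fit, t + h) - predict_trajectory(fit, t - h)) -
     (predict_trajectory(fit, t + 2 * h) - predict_trajectory(fit, t - 2 * h))) /
    (12 * h)
}

#' Sensitivity-to-change curve
#'
#' Slope of the estimated trajectory divided by the residual SD (subject
#' intercepts removed): the per-year signal-to-noise ratio for measuring
#' individual change.
#'
#' @param fit A [fit_trajectory()] fit (REML residual SD is used).
#' @param t Disease-time grid.
#' @return d theta-hat / dt divided by sigma-hat.
#' @export
sensitivity_curve <- function(fit, t) {
  trajectory_derivative(fit, t) / sqrt(fit$sigma2)
}

# ---- dual-timescale models (age x disease time) ----

dual_design <- function(form, dt, age, at0, dfd, dfa) {
  int <- rep(1, length(dt))
  if (form == "null") return(matrix(int, ncol = 1))
  if (form == "disease_only") return(cbind(int, splines::ns(dt, df = dfd)))
  if (form == "age_only") return(cbind(int, splines::ns(age, df = dfa)))
  Bd <- splines::ns(dt, df = dfd)
  Ba <- splines::ns(at0, df = dfa)
  if (form == "additive") return(cbind(int, Bd, Ba))
  # interaction: bilinear expansion of centred disease and age terms plus
  # the main effects (centring reduces collinearity with the main effects)
  Bdc <- sweep(Bd, 2, colMeans(Bd))
  Bac <- sweep(Ba, 2, colMeans(Ba))
  TP <- matrix(0, length(dt), ncol(Bdc) * ncol(Bac))
  idx <- 1L
  for (a in seq_len(ncol(Bdc))) {
    for (b in seq_len(ncol(Bac))) {
      TP[, idx] <- Bdc[, a] * Bac[, b]
      idx <- idx + 1L
    }
  }
  cbind(int, Bd, Ba, TP)
}

#' Dual-timescale models of age and disease time
#'
#' Fits five trajectory forms for an outcome observed over both progressive
#' age and predicted disease time -- null (constant), disease-time only,
#' age only, additive, and interaction -- each with a subject random
#' intercept, over all admissible spline degree-of-freedom combinations
#' (`dof_range` per term), and selects the minimum-BIC candidate under ML.
#' Where both timescales enter, age is represented by age at disease Time 0
#' (`at0`, the subject mean of age minus disease time) so progressive time
#' is not captured twice; progressive age `a_ij` is used when age is the
#' sole predictor. The interaction form adds the bilinear expansion of the
#' centred disease-time and age bases to the additive form.
#'
#' @param staged Data frame with columns `disease_time`, `value`,
#'   `subject_id`, `age_bl`, `visit_years`.
#' @param outcome Label stored with the fit.
#' @param dof_range Spline DoF per term (default 1:6).
#' @return Object of class `dual_fit`: `form`, `dfd`, `dfa`, `bic`,
#'   `candidates` (full BIC table), `fit` (the selected [fit_ri_lmm()]).
#' @export
fit_dual_timescale <- function(staged, outcome = "outcome", dof_range = 1:6) {
  ok <- !is.na(staged$value) & !is.na(staged$disease_time) &
    !is.na(staged$age_bl)
  d <- staged[ok, , drop = FALSE]
  age <- d$age_bl + d$visit_years
  at0_subj <- tapply(age - d$disease_time, d$subject_id, mean)
  at0 <- as.numeric(at0_subj[as.character(d$subject_id)])

  cands <- list(list(form = "null", dfd = NA_integer_, dfa = NA_integer_))
  for (df in dof_range) {
    cands <- c(cands, list(list(form = "disease_only", dfd = df, dfa = NA_integer_),
                           list(form = "age_only", dfd = NA_integer_, dfa = df)))
  }
  for (dfd in dof_range) for (dfa in dof_range) {
    cands <- c(cands, list(list(form = "additive", dfd = dfd, dfa = dfa),
                           list(form = "interaction", dfd = dfd, dfa = dfa)))
  }
  rows <- vector("list", length(cands))
  fits <- vector("list", length(cands))
  for (ci in seq_along(cands)) {
    cc <- cands[[ci]]
    X <- dual_design(cc$form, d$disease_time, age, at0, cc$dfd, cc$dfa)
    f <- tryCatch(fit_ri_lmm(X, d$value, d$subject_id, reml = FALSE),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("dual candidate %s (dfd=%s, dfa=%s) skipped",
                      cc$form, cc$dfd, cc$dfa))
      next
    }
    fits[[ci]] <- f
    rows[[ci]] <- data.frame(form = cc$form, dfd = cc$dfd, dfa = cc$dfa,
                             bic = bic_ri_lmm(f), loglik = f$loglik,
                             npar = f$npar, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0L) stop("all dual-timescale candidates failed",
                                            call. = FALSE)
  best <- which.min(tab$bic)
  sel <- tab[best, ]
  fit_idx <- which(vapply(rows, function(r) !is.null(r), logical(1)))[best]
  structure(list(outcome = outcome, form = sel$form, dfd = sel$dfd,
                 dfa = sel$dfa, bic = sel$bic, candidates = tab,
                 fit = fits[[fit_idx]]),
            class = "dual_fit")
}

#' @export
print.dual_fit <- function(x, ...) {
  cat(sprintf("<dual_fit> %s: selected form '%s' (dfd=%s, dfa=%s), BIC %.1f over %d candidates\n",
              x$outcome, x$form, x$dfd, x$dfa, x$bic, nrow(x$candidates)))
  invisible(x)
}
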