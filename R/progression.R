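# Latent disease-time progression model.
#
# Multivariate nonlinear mixed-effects model: observation j of outcome k on
# subject i is
#   y_ijk = theta_k(t_ij + s_fixed(i) + s_i) + x_ik + e_ijk
# with theta_k a natural cubic spline of the shared latent "disease time",
# s_fixed(i) a fixed shift (baseline-group offset + linear baseline-age
# term, reference group anchored at 0), s_i ~ N(0, shift_var) a subject
# random shift, x_ik a subject random intercept per outcome and e_ijk
# independent Gaussian noise with per-outcome variances.
#
# Estimation is by block coordinate ascent on the penalised marginal
# log-likelihood: (a) given shifts, each outcome's spline + variance
# components are fitted by ML (random effects integrated out); (b) given
# curves and variances, each subject's total shift is updated to the
# posterior mode of its marginal likelihood contribution (grid search plus
# parabolic refinement, current value always retained as a candidate so the
# objective cannot decrease); (c) the fixed-shift regression and the shift
# variance are re-estimated in closed form. Spline knots are refreshed from
# the current shifted-time distribution during early iterations and then
# frozen, after which every step monotonically increases the objective.

ns_basis <- function(x, knots, boundary) {
  splines::ns(x, knots = knots, Boundary.knots = boundary)
}

make_knots <- function(x, dof) {
  boundary <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  # cap the basis dimension by the distinct support so the design stays
  # full-rank even when shifted times cluster on few values (early
  # iterations of the alternating fit)
  n_dist <- length(unique(round(x, 6)))
  dof_eff <- max(2L, min(dof, n_dist - 2L))
  probs <- seq_len(dof_eff - 1L) / dof_eff
  knots <- stats::quantile(x[x >= boundary[1] & x <= boundary[2]], probs,
                           names = FALSE)
  knots <- knots[knots > boundary[1] & knots < boundary[2]]
  list(knots = unique(knots), boundary = boundary)
}

# marginal log-likelihood parts for one subject/outcome given residuals
# r (vector), residual variance s2 and intercept variance t2
subject_marginal_ll <- function(r, s2, t2) {
  n <- length(r)
  g <- t2 / s2
  w <- g / (1 + n * g)
  -0.5 * (n * log(2 * pi * s2) + log1p(n * g) +
            (sum(r^2) - w * sum(r)^2) / s2)
}

#' Fit the latent disease-time progression model
#'
#' Jointly aligns longitudinal outcomes on a latent disease timeline (see
#' the model description above): spline mean trajectories per outcome,
#' group + baseline-age fixed time shifts (reference group = 0), Gaussian
#' subject random shifts, per-subject-per-outcome random intercepts and
#' per-outcome residual variances, all estimated by an alternating
#' maximum-likelihood scheme.
#'
#' @param data Long-format table with columns `subject_id`, `visit_years`,
#'   `group_bl`, `age_bl`, `outcome`, `value`.
#' @param outcomes Character vector (K >= 2 recommended) of outcomes to
#'   model jointly.
#' @param dof Spline degrees of freedom per outcome trajectory (default 9).
#' @param reference Reference baseline group whose fixed shift is 0.
#' @param max_iter Maximum outer iterations.
#' @param tol Convergence tolerance on the penalised log-likelihood.
#' @param grid_step Step (years) of the shift-update search grid.
#' @param shift_sd_init Initial SD (years) of the subject shift prior.
#' @param knot_refresh Number of initial iterations during which knots are
#'   refreshed from the current shifted times (frozen afterwards).
#' @param on_nonconvergence `"warning"` or `"error"`.
#' @return Object of class `progression_fit`: per-outcome `theta` (spline
#'   coefficients + knots), `group_offsets` (reference = 0), `age_slope`,
#'   `age_center`, `shift_var`, `resid_vars`, `intercept_vars`,
#'   `intercept_cov` (empirical covariance of predicted intercepts),
#'   `shifts` (per-subject fixed/random/total), `loglik_trace`,
#'   `time_zero_offset` (0 until anchored), `converged`.
#' @export
fit_progression <- function(data, outcomes, dof = 9L, reference = "CU-Ab-",
                            max_iter = 60L, tol = 1e-6, grid_step = 0.25,
                            shift_sd_init = 3, knot_refresh = 10L,
                            on_nonconvergence = c("warning", "error")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (length(outcomes) < 1L) stop("need at least one outcome", call. = FALSE)
  if (length(outcomes) == 1L) {
    warning("shifts weakly identified with a single outcome")
  }
  d <- data[data$outcome %in% outcomes & !is.na(data$value), , drop = FALSE]
  subj <- unique(d[, c("subject_id", "group_bl", "age_bl")])
  if (anyDuplicated(subj$subject_id)) {
    stop("inconsistent group/age within subject", call. = FALSE)
  }
  if (!reference %in% subj$group_bl) {
    stop_field("reference", "group not present in data")
  }
  ns_ <- nrow(subj)
  subj$idx <- seq_len(ns_)
  groups <- c(reference, setdiff(sort(unique(subj$group_bl)), reference))
  subj$group_bl <- factor(subj$group_bl, levels = groups)
  age_center <- mean(subj$age_bl)
  age_c <- subj$age_bl - age_center

  per_k <- lapply(outcomes, function(k) {
    dk <- d[d$outcome == k, , drop = FALSE]
    list(y = dk$value, t = dk$visit_years,
         si = subj$idx[match(dk$subject_id, subj$subject_id)])
  })
  names(per_k) <- outcomes

  u <- numeric(ns_)                      # total shift per subject
  m <- numeric(ns_)                      # fixed part
  shift_var <- shift_sd_init^2
  theta <- vector("list", length(outcomes)); names(theta) <- outcomes
  s2 <- t2 <- stats::setNames(numeric(length(outcomes)), outcomes)
  Xfix <- if (length(groups) > 1L) {
    stats::model.matrix(~ group_bl + age_c,
                        data.frame(group_bl = subj$group_bl, age_c = age_c))
  } else {
    cbind(`(Intercept)` = rep(1, ns_), age_c = age_c)
  }

  fit_splines <- function(u, refresh) {
    ll <- 0
    for (k in outcomes) {
      pk <- per_k[[k]]
      x <- pk$t + u[pk$si]
      if (refresh || is.null(theta[[k]])) {
        kn <- make_knots(x, dof)
      } else {
        kn <- theta[[k]][c("knots", "boundary")]
      }
      B <- cbind(1, ns_basis(x, kn$knots, kn$boundary))
      f <- fit_ri_lmm(B, pk$y, pk$si, reml = FALSE)
      theta[[k]] <<- list(beta = f$beta, knots = kn$knots,
                          boundary = kn$boundary)
      s2[k] <<- f$sigma2; t2[k] <<- f$tau2
      ll <- ll + f$loglik
    }
    ll
  }

  # log-likelihood of all subjects' data as a function of candidate shifts,
  # evaluated on a common grid (matrix n_subjects x n_grid). Once knots are
  # frozen the grid basis matrices are constant and cached.
  basis_cache <- new.env(parent = emptyenv())
  ll_on_grid <- function(grid, cache_ok) {
    tot <- matrix(0, ns_, length(grid))
    for (k in outcomes) {
      pk <- per_k[[k]]
      th <- theta[[k]]
      B <- if (cache_ok && !is.null(basis_cache[[k]])) {
        basis_cache[[k]]
      } else {
        xx <- outer(pk$t, grid, `+`)
        Bk <- cbind(1, ns_basis(as.vector(xx), th$knots, th$boundary))
        if (cache_ok) basis_cache[[k]] <- Bk
        Bk
      }
      pred <- B %*% th$beta
      r <- pk$y - matrix(pred, nrow = length(pk$y))
      g <- t2[k] / s2[k]
      lv <- sort(unique(pk$si))
      ssq <- rowsum(r^2, pk$si, reorder = TRUE)
      sm <- rowsum(r, pk$si, reorder = TRUE)
      nik <- as.numeric(table(pk$si)[as.character(lv)])
      w <- g / (1 + nik * g)
      contrib <- matrix(0, ns_, length(grid))
      contrib[lv, ] <- -0.5 * (nik * log(2 * pi * s2[k]) +
                                 log1p(nik * g) +
                                 (ssq - w * sm^2) / s2[k])
      tot <- tot + contrib
    }
    tot
  }

  # per-subject marginal log-likelihood at subject-specific shifts (one
  # basis evaluation per outcome for the whole cohort)
  ll_all_at <- function(u_vec) {
    tot <- numeric(ns_)
    for (k in outcomes) {
      pk <- per_k[[k]]
      th <- theta[[k]]
      pred <- as.numeric(cbind(1, ns_basis(pk$t + u_vec[pk$si], th$knots,
                                           th$boundary)) %*% th$beta)
      r <- pk$y - pred
      g <- t2[k] / s2[k]
      lv <- sort(unique(pk$si))
      ssq <- rowsum(r^2, pk$si, reorder = TRUE)[, 1]
      sm <- rowsum(r, pk$si, reorder = TRUE)[, 1]
      nik <- as.numeric(table(pk$si)[as.character(lv)])
      w <- g / (1 + nik * g)
      tot[lv] <- tot[lv] - 0.5 * (nik * log(2 * pi * s2[k]) +
                                    log1p(nik * g) + (ssq - w * sm^2) / s2[k])
    }
    tot
  }

  penalty <- function(u, m, shift_var) {
    s <- u - m
    sum(-0.5 * (log(2 * pi * shift_var) + s^2 / shift_var))
  }

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    refresh <- it <= knot_refresh
    ll_fit <- fit_splines(u, refresh)

    # objective at the consistent state (theta refitted, shifts current);
    # every subsequent step is coordinate ascent on this quantity
    trace <- c(trace, ll_fit + penalty(u, m, shift_var))
    if (it > knot_refresh + 1L &&
        abs(trace[it] - trace[it - 1L]) < tol * (abs(trace[it]) + 1)) {
      converged <- TRUE
      break
    }

    # (b) shift update on a common grid + parabolic refinement; the grid is
    # frozen together with the knots so grid bases can be cached
    if (refresh || !exists("grid", inherits = FALSE)) {
      sd_s <- sqrt(shift_var)
      grid <- seq(min(m) - 5 * sd_s - 2, max(m) + 5 * sd_s + 2, by = grid_step)
    }
    ll_grid <- ll_on_grid(grid, cache_ok = !refresh) -
      0.5 * (log(2 * pi * shift_var) +
               outer(m, grid, function(mi, g) (g - mi)^2) / shift_var)
    best <- max.col(ll_grid, ties.method = "first")
    u_new <- grid[best]
    # parabolic refinement around the grid argmax; the current value is
    # always a candidate, so the per-subject objective cannot decrease
    bm <- pmin(pmax(best, 2L), length(grid) - 1L)
    l0 <- ll_grid[cbind(seq_len(ns_), bm - 1L)]
    l1 <- ll_grid[cbind(seq_len(ns_), bm)]
    l2 <- ll_grid[cbind(seq_len(ns_), bm + 1L)]
    denom <- l0 - 2 * l1 + l2
    shift <- ifelse(denom < 0, pmin(pmax(0.5 * (l0 - l2) / denom, -1), 1), 0)
    u_ref <- grid[bm] + shift * grid_step
    cand <- cbind(u, u_new, u_ref)
    val <- apply(cand, 2, function(uc) {
      ll_all_at(uc) - 0.5 * (uc - m)^2 / shift_var
    })
    pick <- max.col(val, ties.method = "first")
    u <- cand[cbind(seq_len(ns_), pick)]

    # (c) fixed-shift regression + shift variance (closed-form ML)
    cf <- stats::lm.fit(Xfix, u)
    m <- as.numeric(cf$fitted.values)
    shift_var <- max(mean((u - m)^2), 1e-8)
  }
  if (!converged) {
    msg <- sprintf("progression fit did not converge in %d iterations (last delta %.3g)",
                   max_iter, if (length(trace) > 1) diff(utils::tail(trace, 2)) else NA)
    if (on_nonconvergence == "error") stop(msg, call. = FALSE) else warning(msg)
  }

  # anchor: reference-group fixed shift = 0 (translate the timeline)
  cf <- stats::lm.fit(Xfix, u)
  beta_fix <- cf$coefficients
  beta_fix[is.na(beta_fix)] <- 0  # unidentifiable terms (e.g. constant age)
  c0 <- beta_fix[1]
  u <- u - c0; m <- m - c0
  for (k in outcomes) {
    theta[[k]]$knots <- theta[[k]]$knots - c0
    theta[[k]]$boundary <- theta[[k]]$boundary - c0
  }
  group_offsets <- if (length(groups) > 1L) {
    stats::setNames(c(0, beta_fix[2:length(groups)]), groups)
  } else {
    stats::setNames(0, groups)
  }
  age_slope <- unname(beta_fix[length(groups) + 1L])

  # empirical covariance of predicted random intercepts across outcomes
  blups <- sapply(outcomes, function(k) {
    pk <- per_k[[k]]
    th <- theta[[k]]
    pred <- cbind(1, ns_basis(pk$t + u[pk$si], th$knots, th$boundary)) %*%
      th$beta
    r <- pk$y - pred
    g <- t2[k] / s2[k]
    sm <- rowsum(r, factor(pk$si, levels = seq_len(ns_)))
    nik <- as.numeric(table(factor(pk$si, levels = seq_len(ns_))))
    out <- rep(NA_real_, ns_)
    has <- nik > 0
    out[has] <- g / (1 + nik[has] * g) * sm[has]
    out
  })
  intercept_cov <- stats::cov(blups, use = "pairwise.complete.obs")

  structure(list(
    outcomes = outcomes, dof = dof, theta = theta,
    group_offsets = group_offsets, age_slope = age_slope,
    age_center = age_center, reference = reference,
    shift_var = shift_var, resid_vars = s2, intercept_vars = t2,
    intercept_cov = intercept_cov,
    shifts = data.frame(subject_id = subj$subject_id,
                        group_bl = as.character(subj$group_bl),
                        age_bl = subj$age_bl,
                        shift_fixed = m, shift_random = u - m,
                        shift_total = u, stringsAsFactors = FALSE),
    loglik_trace = trace, time_zero_offset = 0,
    converged = converged, n_iter = length(trace)
  ), class = "progression_fit")
}

#' @export
print.progression_fit <- function(x, ...) {
  cat(sprintf("<progression_fit> %d outcomes, %d subjects, shift SD %.2f y, %s after %d iterations\n",
              length(x$outcomes), nrow(x$shifts), sqrt(x$shift_var),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Evaluate a fitted mean trajectory on the disease-time scale
#'
#' @param fit A [fit_progression()] fit.
#' @param outcome Outcome name.
#' @param t Disease times (on the anchored scale if the fit was anchored).
#' @return Numeric vector theta_k(t).
#' @export
eval_trajectory <- function(fit, outcome, t) {
  th <- fit$theta[[outcome]]
  if (is.null(th)) stop_field("outcome", "not in fit")
  tt <- t - fit$time_zero_offset
  as.numeric(cbind(1, ns_basis(tt, th$knots, th$boundary)) %*% th$beta)
}

#' Predict disease times for subjects
#'
#' Computes `t_ij + s_fixed(i) + s_i` per observation, where the fixed shift
#' uses the fitted group offsets and age slope and `s_i` is the maximum a
#' posteriori value of the subject random shift given the subject's
#' observations under the fitted parameters. Subjects with no usable
#' observations are staged on the fixed effect only (`s_i = 0`) and flagged.
#'
#' @param fit A [fit_progression()] fit.
#' @param data Long-format table (same schema as for [fit_progression()]).
#' @param grid_step Search grid step (years) for the posterior mode.
#' @return `data` with columns `disease_time` and `staging` (`"map"` or
#'   `"fixed_only"`) appended; per-subject shifts in attribute `"shifts"`.
#' @export
predict_disease_time <- function(fit, data, grid_step = 0.1) {
  stopifnot(inherits(fit, "progression_fit"))
  subj <- unique(data[, c("subject_id", "group_bl", "age_bl")])
  off <- fit$group_offsets[as.character(subj$group_bl)]
  if (anyNA(off)) stop("unknown baseline group in data", call. = FALSE)
  m <- unname(off) + fit$age_slope * (subj$age_bl - fit$age_center)
  ns_ <- nrow(subj)
  sidx <- stats::setNames(seq_len(ns_), subj$subject_id)
  sd_s <- sqrt(fit$shift_var)

  # vectorised posterior log-density of every subject over a common grid of
  # candidate random shifts
  per_k <- lapply(fit$outcomes, function(k) {
    sel <- data$outcome == k & !is.na(data$value)
    list(y = data$value[sel], t = data$visit_years[sel],
         si = unname(sidx[data$subject_id[sel]]))
  })
  names(per_k) <- fit$outcomes
  # data log-likelihood only (the shift prior is added by the caller);
  # column j uses shift m_i + offsets[i] + sgrid[j] for subject i
  ll_grid <- function(sgrid, offsets = 0) {
    tot <- matrix(0, ns_, length(sgrid))
    offsets <- rep_len(offsets, ns_)
    for (k in fit$outcomes) {
      pk <- per_k[[k]]
      if (length(pk$y) == 0L) next
      th <- fit$theta[[k]]
      s2 <- fit$resid_vars[[k]]; g <- fit$intercept_vars[[k]] / s2
      xx <- outer(pk$t + m[pk$si] + offsets[pk$si], sgrid, `+`)
      pred <- cbind(1, ns_basis(as.vector(xx), th$knots, th$boundary)) %*%
        th$beta
      r <- pk$y - matrix(pred, nrow = length(pk$y))
      lv <- sort(unique(pk$si))
      ssq <- rowsum(r^2, pk$si, reorder = TRUE)
      sm <- rowsum(r, pk$si, reorder = TRUE)
      nik <- as.numeric(table(pk$si)[as.character(lv)])
      w <- g / (1 + nik * g)
      tot[lv, ] <- tot[lv, ] - 0.5 * (nik * log(2 * pi * s2) +
                                        log1p(nik * g) +
                                        (ssq - w * sm^2) / s2)
    }
    tot
  }

  has_obs <- rep(FALSE, ns_)
  for (k in fit$outcomes) has_obs[unique(per_k[[k]]$si)] <- TRUE
  if (sd_s < 1e-4 || !any(has_obs)) {
    s <- numeric(ns_)
  } else {
    prior <- function(sval) -0.5 * sval^2 / fit$shift_var
    step1 <- min(grid_step, sd_s)
    coarse <- sort(c(0, seq(-4.5 * sd_s, 4.5 * sd_s, by = step1)))
    v1 <- ll_grid(coarse) + matrix(prior(coarse), ns_, length(coarse),
                                   byrow = TRUE)
    b1 <- coarse[max.col(v1, ties.method = "first")]
    # fine grid around each subject's coarse argmax (offsets fold the
    # subject-specific centre into the shared relative grid)
    rel <- seq(-step1, step1, length.out = 21)
    step2 <- rel[2] - rel[1]
    v2 <- ll_grid(rel, offsets = b1) + prior(outer(b1, rel, `+`))
    b2i <- pmin(pmax(max.col(v2, ties.method = "first"), 2L),
                length(rel) - 1L)
    l0 <- v2[cbind(seq_len(ns_), b2i - 1L)]
    l1 <- v2[cbind(seq_len(ns_), b2i)]
    l2 <- v2[cbind(seq_len(ns_), b2i + 1L)]
    den <- l0 - 2 * l1 + l2
    adj <- ifelse(den < 0, pmin(pmax(0.5 * (l0 - l2) / den, -1), 1), 0)
    s <- b1 + rel[b2i] + adj * step2
    # tie convention: a candidate at 0 wins when not materially worse
    v0 <- ll_grid(0)[, 1] + prior(0)
    s[abs(v0 - l1) < 1e-9] <- 0
    s[!has_obs] <- 0
  }
  flag <- ifelse(has_obs, "map", "fixed_only")
  shifts <- data.frame(subject_id = subj$subject_id, shift_fixed = m,
                       shift_random = s, shift_total = m + s,
                       staging = flag, stringsAsFactors = FALSE)
  j <- match(data$subject_id, shifts$subject_id)
  data$disease_time <- data$visit_years + shifts$shift_total[j] +
    fit$time_zero_offset
  data$staging <- shifts$staging[j]
  attr(data, "shifts") <- shifts
  data
}

#' Anchor Time 0 at amyloid abnormality onset
#'
#' Finds the disease time at which the running median of CSF A-beta 1-42
#' first crosses the healthy reference group's extreme quantile in the
#' direction of abnormality (decreasing A-beta: the 95th percentile in the
#' abnormal direction is the 5th raw percentile), and returns the offset
#' that places that crossing at Time 0.
#'
#' @param staged Data frame with columns `disease_time` and `value` (CSF
#'   A-beta observations staged on disease time).
#' @param healthy_values CSF A-beta values of the healthy (amyloid-negative)
#'   reference sample.
#' @param direction Direction of abnormality (default `"decreasing"`).
#' @param window Width (years) of the running-median window.
#' @param grid_step Evaluation grid step (years).
#' @return List with `time_zero` (crossing time on the input scale),
#'   `offset` (= -time_zero), `threshold`.
#' @export
anchor_time_zero <- function(staged, healthy_values,
                             direction = c("decreasing", "increasing"),
                             window = 2, grid_step = 0.05) {
  direction <- match.arg(direction)
  ok <- !is.na(staged$value) & !is.na(staged$disease_time)
  tv <- staged$disease_time[ok]; vv <- staged$value[ok]
  if (length(vv) < 10L) stop("too few observations to anchor", call. = FALSE)
  thr <- if (direction == "decreasing") {
    stats::quantile(healthy_values, 0.05, names = FALSE)
  } else {
    stats::quantile(healthy_values, 0.95, names = FALSE)
  }
  grid <- seq(min(tv), max(tv), by = grid_step)
  med <- vapply(grid, function(g) {
    sel <- abs(tv - g) <= window / 2
    if (sum(sel) < 5L) NA_real_ else stats::median(vv[sel])
  }, numeric(1))
  crossed <- if (direction == "decreasing") med <= thr else med >= thr
  hit <- which(!is.na(crossed) & crossed)
  if (length(hit) == 0L) stop("cannot anchor: threshold never crossed",
                              call. = FALSE)
  # first-crossing convention (ties/flat segments resolve to the earliest
  # grid point at or beyond the threshold)
  t0 <- grid[hit[1]]
  list(time_zero = t0, offset = -t0, threshold = thr)
}

#' Apply a Time-0 anchoring offset to a progression fit
#'
#' @param fit A [fit_progression()] fit.
#' @param offset Offset (years) added to all predicted disease times.
#' @return The fit with `time_zero_offset` updated.
#' @export
apply_anchor <- function(fit, offset) {
  stopifnot(inherits(fit, "progression_fit"))
  fit$time_zero_offset <- fit$time_zero_offset + offset
  fit
}

#' Serialise a progression fit to JSON
#'
#' @param fit A [fit_progression()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_progression_json <- function(fit, path) {
  jsonlite::write_json(list(
    outcomes = fit$outcomes, dof = fit$dof,
    theta = lapply(fit$theta, function(th) list(
      beta = th$beta, knots = th$knots, boundary = th$boundary)),
    group_offsets = as.list(fit$group_offsets), age_slope = fit$age_slope,
    age_center = fit$age_center, shift_var = fit$shift_var,
    resid_vars = as.list(fit$resid_vars),
    intercept_vars = as.list(fit$intercept_vars),
    intercept_cov = fit$intercept_cov,
    time_zero_offset = fit$time_zero_offset,
    shifts = fit$shifts, converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
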