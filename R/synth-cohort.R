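#' Default outcome parameters for the synthetic cohort generator
#'
#' Mean curves are monotone control-point interpolants over latent disease
#' time (years): cognition worsens (ADAS13 and CDR-SB rise, MMSE falls),
#' amyloid PET centiloid rises and CSF A-beta 1-42 falls as disease advances.
#' Floors/ceilings reflect the instruments (MMSE 0-30, ADAS13 0-85, CDR-SB
#' 0-18); centiloid and CSF A-beta are unbounded above. Values are synthetic
#' defaults chosen to look like an aging/AD observational cohort; they are
#' not estimates from any real dataset.
#'
#' @return Named list, one element per outcome, each with `times`, `values`
#'   (control points), `floor`, `ceiling`, `intercept_sd` (subject random
#'   intercept SD) and `resid_sd` (residual SD), all on the outcome's scale.
#' @export
default_outcome_params <- function() {
  list(
    adas13 = list(
      times = c(-12, -4, 0, 4, 8, 12, 16),
      values = c(8, 9, 10, 12, 17, 26, 36),
      floor = 0, ceiling = 85, intercept_sd = 3, resid_sd = 3
    ),
    cdrsb = list(
      times = c(-12, -4, 0, 4, 8, 12, 16),
      values = c(0.05, 0.1, 0.3, 0.9, 2.5, 5.5, 9.5),
      floor = 0, ceiling = 18, intercept_sd = 0.4, resid_sd = 0.8
    ),
    mmse = list(
      times = c(-12, -4, 0, 4, 8, 12, 16),
      values = c(29, 28.8, 28.4, 27.6, 25.5, 22, 17.5),
      floor = 0, ceiling = 30, intercept_sd = 1, resid_sd = 1.5
    ),
    centiloid = list(
      times = c(-12, -4, 0, 4, 8, 12, 16),
      values = c(-5, 8, 28, 55, 78, 95, 105),
      floor = -Inf, ceiling = Inf, intercept_sd = 10, resid_sd = 10
    ),
    csf_ab42 = list(
      times = c(-12, -4, 0, 4, 8, 12, 16),
      values = c(1450, 1250, 1020, 830, 700, 620, 580),
      floor = 0, ceiling = Inf, intercept_sd = 120, resid_sd = 100
    )
  )
}

#' Specify a synthetic longitudinal cohort
#'
#' Defines the generating process for an observational aging-cohort style
#' long-format table
#' with four baseline groups on a shared latent disease timeline. Each
#' subject's latent time shift is `shift_mean_by_group[g] +
#' age_shift_slope * (age_bl - age_mean) + s_i` with `s_i ~ N(0, shift_sd^2)`;
#' an observation of outcome k at visit time t is
#' `curve_k(t + shift) + x_ik + e`, truncated at the outcome's floor/ceiling.
#'
#' @param n_per_group Subjects per baseline group (single count, or a named
#'   vector over the four groups).
#' @param visit_schedule Nominal visit times in years since baseline,
#'   strictly increasing, starting at 0.
#' @param dropout_rate Per-visit probability of (monotone) dropout after
#'   baseline.
#' @param mcar_rate Outcome-level missing-completely-at-random rate.
#' @param shift_mean_by_group Mean latent shift (years) per group. Defaults
#'   place cognitively unimpaired amyloid-negative subjects well before
#'   amyloid onset and dementia subjects about a decade after, spanning a
#'   roughly 20-year continuum.
#' @param shift_sd SD (years) of the subject-level random shift.
#' @param age_shift_slope Additional latent shift per year of baseline age.
#' @param outcome_params See [default_outcome_params()].
#' @param age_mean,age_sd Baseline age distribution (normal, truncated to
#'   55-95 years).
#' @param n_sites Number of scan sites (uniform assignment).
#' @param site_sd SD of a site random intercept added to every outcome (on a
#'   standardised scale: the site effect is `site_sd * resid_sd` per outcome).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 100,
                        visit_schedule = c(0, 0.5, 1, 2, 3, 4),
                        dropout_rate = 0.12,
                        mcar_rate = 0.02,
                        shift_mean_by_group = c("CU-Ab-" = -6, "CU-Ab+" = 0,
                                                "MCI-Ab+" = 5.5, "ADD-Ab+" = 10),
                        shift_sd = 3,
                        age_shift_slope = 0.1,
                        outcome_params = default_outcome_params(),
                        age_mean = 73, age_sd = 7,
                        n_sites = 10, site_sd = 0.1,
                        seed = 1L) {
  groups <- c("CU-Ab-", "CU-Ab+", "MCI-Ab+", "ADD-Ab+")
  if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(n_per_group, 4L), groups)
  }
  if (is.null(names(n_per_group)) || !setequal(names(n_per_group), groups)) {
    stop_field("n_per_group", "must be a single count or named over the four groups")
  }
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 1)) stop_field("n_per_group", "must be >= 1 per group")
  if (length(visit_schedule) < 1L || is.unsorted(visit_schedule, strictly = TRUE)) {
    stop_field("visit_schedule", "must be strictly increasing")
  }
  check_scalar_num(dropout_rate, "dropout_rate", 0, 1)
  check_scalar_num(mcar_rate, "mcar_rate", 0, 1)
  check_scalar_num(shift_sd, "shift_sd")
  if (shift_sd <= 0) stop_field("shift_sd", "must be > 0")
  if (is.null(names(shift_mean_by_group)) ||
      !setequal(names(shift_mean_by_group), groups)) {
    stop_field("shift_mean_by_group", "must be named over the four groups")
  }
  check_scalar_num(age_sd, "age_sd", 0)
  check_scalar_num(n_sites, "n_sites", 1)
  for (nm in names(outcome_params)) {
    p <- outcome_params[[nm]]
    need <- c("times", "values", "floor", "ceiling", "intercept_sd", "resid_sd")
    if (!all(need %in% names(p))) {
      stop_field(paste0("outcome_params$", nm), "missing control fields")
    }
    if (p$floor >= p$ceiling) {
      stop_field(paste0("outcome_params$", nm), "floor must be < ceiling")
    }
    if (length(p$times) != length(p$values) || is.unsorted(p$times, strictly = TRUE)) {
      stop_field(paste0("outcome_params$", nm),
                 "control times must be strictly increasing and match values")
    }
  }
  structure(list(
    n_per_group = n_per_group, visit_schedule = visit_schedule,
    dropout_rate = dropout_rate, mcar_rate = mcar_rate,
    shift_mean_by_group = shift_mean_by_group[groups], shift_sd = shift_sd,
    age_shift_slope = age_shift_slope, outcome_params = outcome_params,
    age_mean = age_mean, age_sd = age_sd, n_sites = n_sites,
    site_sd = site_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a long-format visit-level table plus the generating ground truth
#' (latent shifts and subject intercepts), so latent disease-time estimation
#' can be validated against known values.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{data}{long-format `data.frame` with columns `subject_id`,
#'       `visit_years`, `group_bl`, `age_bl`, `sex`, `education`, `icv`,
#'       `site`, `outcome`, `value`.}
#'     \item{truth}{list with `subjects` (per-subject `group_bl`, `age_bl`,
#'       `shift_fixed`, `shift_random`, `shift_total`) and `intercepts`
#'       (subject x outcome matrix of random intercepts).}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_per_group)
  n <- sum(spec$n_per_group)
  outcomes <- names(spec$outcome_params)
  curves <- lapply(spec$outcome_params,
                   function(p) monotone_curve(p$times, p$values))

  with_seed(spec$seed, {
    group <- rep(groups, times = spec$n_per_group)
    id <- sprintf("S%04d", seq_len(n))
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    # truncate to a plausible elderly-cohort range
    while (any(bad <- age < 55 | age > 95)) {
      age[bad] <- stats::rnorm(sum(bad), spec$age_mean, spec$age_sd)
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    education <- pmin(pmax(round(stats::rnorm(n, 16, 2.6)), 6), 20)
    icv <- stats::rnorm(n, 1.5e6, 1.5e5)
    site <- sprintf("site%02d", sample.int(spec$n_sites, n, replace = TRUE))
    site_eff <- stats::rnorm(spec$n_sites, 0, spec$site_sd)

    s_random <- stats::rnorm(n, 0, spec$shift_sd)
    shift_fixed <- spec$shift_mean_by_group[group] +
      spec$age_shift_slope * (age - spec$age_mean)
    shift_total <- shift_fixed + s_random

    xint <- sapply(outcomes, function(k) {
      stats::rnorm(n, 0, spec$outcome_params[[k]]$intercept_sd)
    })
    if (is.null(dim(xint))) xint <- matrix(xint, nrow = n,
                                           dimnames = list(NULL, outcomes))
    rownames(xint) <- id

    # monotone dropout: subject retained through visit j with prob (1-rate)^(j-1)
    nv <- length(spec$visit_schedule)
    keep_until <- 1L + stats::rgeom(n, prob = max(spec$dropout_rate, 1e-12))
    if (spec$dropout_rate == 0) keep_until <- rep(nv, n)
    keep_until <- pmin(keep_until, nv)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      vt <- spec$visit_schedule[seq_len(keep_until[i])]
      dt <- vt + shift_total[i]
      per_out <- lapply(outcomes, function(k) {
        p <- spec$outcome_params[[k]]
        mu <- curves[[k]](dt) + xint[i, k] +
          site_eff[as.integer(sub("site", "", site[i]))] * p$resid_sd
        val <- mu + stats::rnorm(length(dt), 0, p$resid_sd)
        pmin(pmax(val, p$floor), p$ceiling)
      })
      rows[[i]] <- data.frame(
        subject_id = id[i], visit_years = rep(vt, times = length(outcomes)),
        group_bl = group[i], age_bl = age[i], sex = sex[i],
        education = education[i], icv = icv[i], site = site[i],
        outcome = rep(outcomes, each = length(vt)),
        value = unlist(per_out),
        stringsAsFactors = FALSE
      )
    }
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    if (spec$mcar_rate > 0) {
      drop <- stats::runif(nrow(data)) < spec$mcar_rate
      data <- data[!drop, , drop = FALSE]
    }
    list(
      data = data,
      truth = list(
        subjects = data.frame(
          subject_id = id, group_bl = group, age_bl = age,
          shift_fixed = unname(shift_fixed), shift_random = s_random,
          shift_total = unname(shift_total), stringsAsFactors = FALSE
        ),
        intercepts = xint,
        curves = curves
      )
    )
  })
}
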