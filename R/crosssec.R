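#' Classify amyloid status from CSF and PET measures
#'
#' CSF A-beta 1-42 takes precedence where available: values below the
#' threshold (default 980 pg/mL, Elecsys scale) are positive, above are
#' negative, and values within `borderline_frac` (default 5%) of the
#' threshold are excluded as borderline to limit misclassification noise.
#' Where CSF is missing, the PET centiloid rule is applied with the same
#' borderline band around `centiloid_threshold` (the centiloid cutpoint is a
#' configuration choice, not a fixed constant of the method). Subjects with
#' neither measure are `unknown`.
#'
#' @param csf_ab42 CSF A-beta 1-42 (pg/mL), NA where unavailable.
#' @param centiloid Amyloid PET centiloid, NA where unavailable.
#' @param csf_threshold CSF positivity threshold (pg/mL).
#' @param borderline_frac Half-width of the exclusion band, as a fraction of
#'   the threshold.
#' @param centiloid_threshold PET centiloid positivity threshold.
#' @return Factor with levels `negative`, `positive`, `excluded_borderline`,
#'   `unknown`.
#' @export
classify_amyloid <- function(csf_ab42, centiloid = NULL,
                             csf_threshold = 980, borderline_frac = 0.05,
                             centiloid_threshold = 20) {
  n <- max(length(csf_ab42), length(centiloid))
  if (is.null(centiloid)) centiloid <- rep(NA_real_, n)
  csf_ab42 <- rep_len(csf_ab42, n); centiloid <- rep_len(centiloid, n)
  if (any(csf_ab42 < 0, na.rm = TRUE)) {
    stop_field("csf_ab42", "concentrations must be non-negative")
  }
  out <- rep("unknown", n)
  lo_c <- csf_threshold * (1 - borderline_frac)
  hi_c <- csf_threshold * (1 + borderline_frac)
  has_csf <- !is.na(csf_ab42)
  out[has_csf & csf_ab42 < lo_c] <- "positive"
  out[has_csf & csf_ab42 > hi_c] <- "negative"
  out[has_csf & csf_ab42 >= lo_c & csf_ab42 <= hi_c] <- "excluded_borderline"
  use_pet <- !has_csf & !is.na(centiloid)
  lo_p <- centiloid_threshold * (1 - borderline_frac)
  hi_p <- centiloid_threshold * (1 + borderline_frac)
  out[use_pet & centiloid > hi_p] <- "positive"
  out[use_pet & centiloid < lo_p] <- "negative"
  out[use_pet & centiloid >= lo_p & centiloid <= hi_p] <- "excluded_borderline"
  factor(out, levels = c("negative", "positive", "excluded_borderline", "unknown"))
}

#' Flag outliers by the mean +/- k IQR rule
#'
#' Flags values outside `mean +/- iqr_mult * IQR`. The default multiplier
#' (1.5) and a mean-centred fence follow the analysis convention used for
#' cross-sectional models; `method = "tukey"` gives the conventional
#' quartile-based fence instead. With IQR = 0 only values equal to the mean
#' (or, for `"tukey"`, the quartiles) are kept.
#'
#' @param values Numeric vector (n >= 4).
#' @param iqr_mult Fence multiplier.
#' @param method `"mean_iqr"` (default) or `"tukey"`.
#' @return List with `values` (non-flagged values) and `flags` (logical).
#' @export
exclude_outliers <- function(values, iqr_mult = 1.5,
                             method = c("mean_iqr", "tukey")) {
  method <- match.arg(method)
  if (sum(!is.na(values)) < 4L) stop("need at least 4 non-missing values",
                                     call. = FALSE)
  iqr <- stats::IQR(values, na.rm = TRUE)
  if (method == "mean_iqr") {
    ctr <- mean(values, na.rm = TRUE)
    lo <- ctr - iqr_mult * iqr; hi <- ctr + iqr_mult * iqr
  } else {
    q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    lo <- q[1] - iqr_mult * iqr; hi <- q[2] + iqr_mult * iqr
  }
  flags <- !is.na(values) & (values < lo | values > hi)
  list(values = values[!flags & !is.na(values)], flags = flags)
}

#' Holm (or Benjamini-Hochberg) p-value adjustment
#'
#' Thin wrapper over [stats::p.adjust()] fixing the family conventions used
#' throughout the package: Holm step-down by default, Benjamini-Hochberg
#' available by configuration.
#'
#' @param p Numeric vector of p-values.
#' @param method `"holm"` (default) or `"BH"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("holm", "BH")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

#' Cohen's d for two samples
#'
#' Standardised mean difference with the pooled SD.
#'
#' @param x,y Numeric vectors.
#' @return Cohen's d (mean(x) - mean(y), standardised).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

# Cohen's f from group sizes, adjusted group means and residual SD:
# f = sigma_between / sigma_resid with sigma_between the (weighted)
# population SD of group means.
cohens_f_from_means <- function(means, ns, sigma) {
  mbar <- sum(ns * means) / sum(ns)
  sqrt(sum(ns * (means - mbar)^2) / sum(ns)) / sigma
}

# order group levels along the disease continuum where recognised,
# alphabetically otherwise (keeps the healthy group as the reference)
canonical_groups <- function(g) {
  if (is.factor(g)) return(droplevels(g))
  canon <- c("CU-Ab-", "CU-Ab+", "MCI-Ab+", "ADD-Ab+")
  present <- unique(g)
  lev <- c(canon[canon %in% present], sort(setdiff(present, canon)))
  factor(g, levels = lev)
}

group_model_formula <- function(outcome, with_site) {
  rhs <- "group_bl + age_bl + sex + education + icv"
  if (with_site) rhs <- paste(rhs, "+ (1 | site)")
  stats::as.formula(paste(outcome, "~", rhs))
}

#' Baseline group comparison via a mixed-effects model
#'
#' Fits `outcome ~ group + baseline age + sex + education + ICV + (1 | site)`
#' on a baseline table and returns marginal F tests per fixed term
#' (Satterthwaite denominator degrees of freedom), Cohen's f for the group
#' term, and the model's adjusted group means. With fewer than 2 sites the
#' site random intercept is dropped with a warning and an ordinary linear
#' model is used (F tests with residual df).
#'
#' @param data Baseline data frame with columns `group_bl`, `age_bl`, `sex`,
#'   `education`, `icv`, `site` and the outcome.
#' @param outcome Name of the outcome column.
#' @return Object of class `group_model_result`: `outcome`, `anova` (term,
#'   F, df1, df2, p), `cohens_f`, `group_means`, `sigma`, `site_sd`, `fit`.
#' @export
fit_group_model <- function(data, outcome) {
  need <- c("group_bl", "age_bl", "sex", "education", "icv", "site", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop(sprintf("missing column(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  data$group_bl <- canonical_groups(data$group_bl)
  # ICV is ~1e6 mm^3; rescale for numerical conditioning (F tests invariant)
  data$icv <- data$icv / stats::sd(data$icv)
  if (nlevels(data$group_bl) < 2L) stop("need at least 2 groups", call. = FALSE)
  n_sites <- length(unique(data$site))
  with_site <- n_sites >= 2L
  if (!with_site) warning("fewer than 2 sites; site random intercept dropped")

  # rank check on the fixed-effects design
  X <- stats::model.matrix(~ group_bl + age_bl + sex + education + icv, data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; aliased column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }

  if (with_site) {
    fit <- lmerTest::lmer(group_model_formula(outcome, TRUE), data = data,
                          REML = TRUE,
                          control = lme4::lmerControl(calc.derivs = FALSE,
                                                      check.conv.singular = "ignore"))
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    tab <- data.frame(term = rownames(an), F = an$`F value`,
                      df1 = an$NumDF, df2 = an$DenDF,
                      p = an$`Pr(>F)`, stringsAsFactors = FALSE)
    sigma <- stats::sigma(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    site_sd <- sqrt(vc$vcov[vc$grp == "site"])
    beta <- lme4::fixef(fit)
  } else {
    fit <- stats::lm(stats::as.formula(
      paste(outcome, "~ group_bl + age_bl + sex + education + icv")), data = data)
    an <- stats::drop1(fit, test = "F")
    an <- an[-1, , drop = FALSE]
    tab <- data.frame(term = rownames(an), F = an$`F value`,
                      df1 = an$Df, df2 = fit$df.residual,
                      p = an$`Pr(>F)`, stringsAsFactors = FALSE)
    sigma <- stats::sigma(fit)
    site_sd <- 0
    beta <- stats::coef(fit)
  }

  # covariate-adjusted group means (at reference covariate values; only
  # differences between groups matter for effect sizes)
  groups <- levels(data$group_bl)
  gm <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups[-1]) {
    nm <- paste0("group_bl", g)
    gm[g] <- beta[[nm]]
  }
  ns <- table(data$group_bl)[groups]
  f <- cohens_f_from_means(gm, as.numeric(ns), sigma)

  structure(list(outcome = outcome, anova = tab, cohens_f = f,
                 group_means = gm, group_ns = as.numeric(ns), sigma = sigma,
                 site_sd = site_sd, n = nrow(data), fit = fit),
            class = "group_model_result")
}

#' Pairwise post-hoc group contrasts
#'
#' Refits the baseline group model restricted to the reference group and one
#' other group at a time, reporting the group-term F test and Cohen's d (the
#' covariate-adjusted group difference standardised by the residual SD).
#' P-values are unadjusted; adjust across the analysis family with
#' [adjust_pvalues()].
#'
#' @param data Baseline table (see [fit_group_model()]).
#' @param outcome Outcome column name.
#' @param reference Reference group (default `"CU-Ab-"`).
#' @param others Groups to compare against the reference (default: all
#'   other groups present).
#' @return Data frame: comparison, F, df1, df2, d, p.
#' @export
pairwise_contrasts <- function(data, outcome, reference = "CU-Ab-",
                               others = NULL) {
  data$group_bl <- factor(data$group_bl)
  if (!reference %in% levels(data$group_bl)) {
    stop_field("reference", "not a group present in the data")
  }
  if (is.null(others)) others <- setdiff(levels(data$group_bl), reference)
  if (reference %in% others) {
    stop("cannot contrast a group with itself", call. = FALSE)
  }
  rows <- lapply(others, function(g) {
    sub <- data[data$group_bl %in% c(reference, g), , drop = FALSE]
    sub$group_bl <- factor(sub$group_bl, levels = c(reference, g))
    res <- fit_group_model(sub, outcome)
    grow <- res$anova[res$anova$term == "group_bl", ]
    d <- unname(res$group_means[g] / res$sigma)
    data.frame(comparison = paste(reference, "vs", g),
               F = grow$F, df1 = grow$df1, df2 = grow$df2,
               d = d, p = grow$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Effect sizes from a fitted group model
#'
#' Returns Cohen's f for the omnibus group effect and, for two-group fits,
#' Cohen's d of the adjusted group difference. For two balanced groups
#' f = d / 2.
#'
#' @param fit A [fit_group_model()] result.
#' @return List with `f` and (two-group fits only) `d`.
#' @export
effect_sizes <- function(fit) {
  stopifnot(inherits(fit, "group_model_result"))
  out <- list(f = fit$cohens_f)
  if (length(fit$group_means) == 2L) {
    out$d <- unname(diff(fit$group_means) / fit$sigma)
  }
  out
}
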