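# Incremental predictive value of texture over volume for future cognition:
# three nested regressions per cognitive score,
#   (1) score ~ score_bl + age_bl + sex + education + icv
#   (2) ... + hv
#   (3) ... + hv + txpc1..txpc5
# compared via bootstrap distributions of adjusted R^2.

#' Build the 2-year cognitive-prediction analysis frame
#'
#' One row per eligible subject (baseline diagnosis without dementia, i.e.
#' CU or MCI groups): the outcome is the score at the follow-up visit
#' closest to `horizon_months` within `window_months` (ties resolved toward
#' the earlier visit); predictors are the baseline score plus baseline
#' covariates and imaging measures supplied in `predictors`.
#'
#' @param cohort Long-format table (columns `subject_id`, `visit_years`,
#'   `group_bl`, `outcome`, `value`).
#' @param predictors Data frame with `subject_id`, `age_bl`, `sex`,
#'   `education`, `icv`, `hv`, `txpc1`..`txpc5`.
#' @param score Cognitive score name (an `outcome` level in `cohort`).
#' @param horizon_months Prediction horizon (default 24).
#' @param window_months Half-width of the follow-up matching window.
#' @param eligible_groups Baseline groups retained (default: the
#'   non-dementia groups).
#' @return Data frame with columns `subject_id`, `y`, `score_bl`, `age_bl`,
#'   `sex`, `education`, `icv`, `hv`, `txpc1`..`txpc5`; subjects dropped for
#'   a missing outcome are counted in attribute `"n_dropped"`.
#' @export
build_prediction_frame <- function(cohort, predictors, score,
                                   horizon_months = 24, window_months = 6,
                                   eligible_groups = c("CU-Ab-", "CU-Ab+",
                                                       "MCI-Ab+")) {
  sc <- cohort[cohort$outcome == score & !is.na(cohort$value), , drop = FALSE]
  sc <- sc[sc$group_bl %in% eligible_groups, , drop = FALSE]
  if (nrow(sc) == 0L) stop("no eligible subjects", call. = FALSE)
  horizon <- horizon_months / 12
  window <- window_months / 12
  ids <- unique(sc$subject_id)
  rows <- lapply(ids, function(id) {
    si <- sc[sc$subject_id == id, , drop = FALSE]
    bl <- si[si$visit_years == 0, , drop = FALSE]
    if (nrow(bl) == 0L) return(NULL)
    fu <- si[abs(si$visit_years - horizon) <= window + 1e-9 &
               si$visit_years > 0, , drop = FALSE]
    if (nrow(fu) == 0L) return(NULL)
    dist <- abs(fu$visit_years - horizon)
    best <- which(dist == min(dist))
    pick <- best[which.min(fu$visit_years[best])]  # tie toward earlier visit
    data.frame(subject_id = id, y = fu$value[pick], score_bl = bl$value[1],
               stringsAsFactors = FALSE)
  })
  frame <- do.call(rbind, rows)
  n_dropped <- length(ids) - if (is.null(frame)) 0L else nrow(frame)
  if (is.null(frame) || nrow(frame) == 0L) stop("no eligible subjects",
                                                call. = FALSE)
  frame <- merge(frame, predictors, by = "subject_id")
  frame <- frame[stats::complete.cases(frame), , drop = FALSE]
  attr(frame, "n_dropped") <- n_dropped
  frame
}

prediction_formulas <- function(tx_cols = paste0("txpc", 1:5)) {
  base <- "y ~ score_bl + age_bl + sex + education + icv"
  list(
    covariates = stats::as.formula(base),
    covariates_hv = stats::as.formula(paste(base, "+ hv")),
    covariates_hv_tx = stats::as.formula(
      paste(base, "+ hv +", paste(tx_cols, collapse = " + ")))
  )
}

#' Bootstrap comparison of nested cognitive-prediction models
#'
#' Draws `n_boot` bootstrap resamples (subjects with replacement), fits the
#' three nested regressions on each, and records adjusted R^2 per model.
#' Model pairs are compared by two-sample t-tests between the bootstrap
#' adjusted-R^2 distributions, Holm-adjusted within the result's family,
#' with Cohen's d of the difference. (Comparing dependent bootstrap
#' distributions by two-sample tests is anti-conservative; a paired
#' alternative is available via `paired = TRUE`.)
#'
#' @param frame A [build_prediction_frame()] result.
#' @param n_boot Bootstrap repetitions (default 1000).
#' @param seed Integer seed (required for reproducibility).
#' @param tx_cols Texture score columns (default `txpc1`..`txpc5`).
#' @param pairs List of model index pairs to compare (defaults to the two
#'   nested steps: volume over covariates, texture over volume).
#' @param paired Use paired t-tests instead of two-sample.
#' @param max_redraw Cap on redraws of degenerate resamples.
#' @return Object of class `comparison_result`: `adj_r2` (n_boot x 3
#'   matrix), `summary` (mean and percentile CI per model), `comparisons`
#'   (t, df, d, p, p_adj per pair), `n_boot`, `n_redrawn`.
#' @export
compare_models <- function(frame, n_boot = 1000L, seed = 1L,
                           tx_cols = paste0("txpc", 1:5),
                           pairs = list(c(1L, 2L), c(2L, 3L)),
                           paired = FALSE, max_redraw = 100L) {
  if (nrow(frame) < 50L) stop("need at least 50 subjects", call. = FALSE)
  fmls <- prediction_formulas(tx_cols)
  # design matrices are built once; bootstrap fits reuse their rows
  Xs <- lapply(fmls, function(fm) {
    stats::model.matrix(stats::update(fm, NULL ~ .), data = frame)
  })
  yv <- frame$y
  # aliased columns are dropped via the effective rank (mirrors lm), so
  # structurally collinear predictor sets degrade gracefully
  adj_r2_fit <- function(X, y) {
    n <- length(y)
    fit <- stats::lm.fit(X, y)
    p <- fit$rank
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss <= 0 || n <= p) return(NA_real_)
    1 - (rss / (n - p)) / (tss / (n - 1))
  }
  r2 <- matrix(NA_real_, n_boot, 3L,
               dimnames = list(NULL, names(fmls)))
  n <- nrow(frame)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(max_redraw)) {
        idx <- sample.int(n, n, replace = TRUE)
        vals <- vapply(Xs, function(X) {
          adj_r2_fit(X[idx, , drop = FALSE], yv[idx])
        }, numeric(1))
        if (!anyNA(vals)) break
        n_redrawn <- n_redrawn + 1L
      }
      r2[b, ] <- vals
    }
  })
  comps <- lapply(pairs, function(pr) {
    a <- r2[, pr[1]]; bb <- r2[, pr[2]]
    if (paired) {
      # treat the paired bootstrap differences as the sampling distribution
      # of the adjusted-R^2 gain: percentile-type two-sided p
      dd <- bb - a
      p <- 2 * min(mean(dd <= 0), mean(dd >= 0))
      p <- min(max(p, 1 / n_boot), 1)
      tt_stat <- mean(dd) / stats::sd(dd)
      df <- NA_real_
      d <- tt_stat
    } else {
      tt <- stats::t.test(bb, a, var.equal = TRUE)
      p <- tt$p.value
      tt_stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      d <- cohens_d(bb, a)
    }
    data.frame(comparison = paste(colnames(r2)[pr[2]], "vs", colnames(r2)[pr[1]]),
               t = tt_stat, df = df, d = d,
               delta_adj_r2 = mean(bb) - mean(a),
               p = p, stringsAsFactors = FALSE)
  })
  comps <- do.call(rbind, comps)
  comps$p_adj <- adjust_pvalues(comps$p)
  summ <- data.frame(
    model = colnames(r2),
    mean_adj_r2 = colMeans(r2),
    ci_lo = apply(r2, 2, stats::quantile, 0.025),
    ci_hi = apply(r2, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(adj_r2 = r2, summary = summ, comparisons = comps,
                 n_boot = n_boot, n = n, n_redrawn = n_redrawn),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d subjects, %d bootstrap resamples\n",
              x$n, x$n_boot))
  print(x$summary, digits = 3)
  print(x$comparisons, digits = 3)
  invisible(x)
}
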