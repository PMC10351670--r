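#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end synthetic pipeline:
#' amyloid thresholds (CSF 980 pg/mL with a 5% borderline exclusion band,
#' configurable centiloid cutpoint), texture settings (32 grey bins,
#' mu +/- 3 sigma trimming), feature cleaning (mean +/- 3 IQR cells,
#' variance < 1e-10 columns), PCA retention (5% variance share), analysis
#' outlier fence (mean +/- 1.5 IQR), spline DoF ranges, bootstrap
#' repetitions and the master seed.
#'
#' @param n_per_group Subjects per baseline group in the simulated cohort.
#' @param visit_schedule Visit times (years).
#' @param seed Master seed (required; every stochastic stage derives its
#'   stream from it).
#' @param bins Grey levels for texture discretisation.
#' @param trim_k SD multiplier for intensity trimming.
#' @param feature_iqr_mult IQR multiplier for feature-cell exclusion.
#' @param analysis_iqr_mult IQR multiplier for analysis outlier exclusion.
#' @param pca_retain Minimum PCA variance share retained.
#' @param csf_threshold,borderline_frac,centiloid_threshold Amyloid rules.
#' @param progression_dof Spline DoF of the latent-time model.
#' @param trajectory_dof_range,dual_dof_range BIC search ranges.
#' @param trajectory_trim Total extreme disease-time quantile excluded.
#' @param n_boot Bootstrap repetitions for the prediction comparison.
#' @param horizon_months,window_months Prediction horizon and matching
#'   window.
#' @param phantom_shape Base phantom grid size (voxels per axis).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 40, visit_schedule = c(0, 1, 2, 3),
                            seed = NULL, bins = 32L, trim_k = 3,
                            feature_iqr_mult = 3, analysis_iqr_mult = 1.5,
                            pca_retain = 0.05, csf_threshold = 980,
                            borderline_frac = 0.05, centiloid_threshold = 20,
                            progression_dof = 9L, progression_max_iter = 150L,
                            trajectory_dof_range = 3:6,
                            dual_dof_range = 1:6, trajectory_trim = 0.05,
                            n_boot = 200L, horizon_months = 24,
                            window_months = 6, phantom_shape = 13L) {
  if (is.null(seed)) stop_field("seed", "a seed is required for stochastic stages")
  for (nm in c("bins", "trim_k", "feature_iqr_mult", "analysis_iqr_mult",
               "pca_retain", "csf_threshold", "borderline_frac",
               "centiloid_threshold", "n_boot")) {
    check_scalar_num(get(nm), nm)
    if (get(nm) <= 0) stop_field(nm, "must be positive")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Phantom specification for one subject-visit at a given disease severity
#'
#' Maps a latent severity in \[0, 1\] to phantom parameters: advancing
#' disease brightens and widens the hyperintense blobs (stronger clustering
#' of bright voxels) and shrinks the ROI, so texture and volume both carry
#' disease signal.
#'
#' @param severity Latent severity in \[0, 1\] (see [pipeline_severity()]).
#' @param base_shape Healthy ROI grid size (voxels per axis).
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
severity_phantom_spec <- function(severity, base_shape, seed) {
  scale <- 1 - 0.12 * severity
  shape <- pmax(9L, as.integer(round(base_shape * scale)))
  phantom_spec(shape = rep(shape, 3),
               base_level = 100,
               cluster_count = 30L,
               blob_sigma = 1.1 + 0.5 * severity,
               blob_amplitude = 6 + 14 * severity,
               noise_sd = 2,
               seed = seed)
}

#' Latent severity from disease time
#'
#' Rescales disease time linearly onto \[0, 1\] over the continuum the
#' synthetic cohort spans, clamping outside `range`.
#'
#' @param disease_time Disease time (years).
#' @param range Disease-time interval mapped to \[0, 1\].
#' @return Severities in \[0, 1\].
#' @export
pipeline_severity <- function(disease_time, range = c(-10, 14)) {
  pmin(pmax((disease_time - range[1]) / diff(range), 0), 1)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate, extract, reduce, cross-sectional models, latent-time
#' staging, trajectory models and the prediction comparison on a synthetic
#' cohort with per-subject-visit texture phantoms, writing all artifacts
#' (CSV tables, JSON models, a manifest with the config hash, seeds, row
#' and exclusion counts) to `out_dir`. Reruns with identical config produce
#' identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("hippotex")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- simulate ----
  cohort <- stage("simulate", {
    spec <- cohort_spec(n_per_group = config$n_per_group,
                        visit_schedule = config$visit_schedule,
                        seed = config$seed)
    generate_cohort(spec)
  })
  write_table_csv(cohort$data, file.path(out_dir, "cohort.csv"))
  write_table_csv(cohort$truth$subjects, file.path(out_dir, "truth_synthetic.csv"))
  manifest$stages$simulate <- list(n_subjects = nrow(cohort$truth$subjects),
                                   n_rows = nrow(cohort$data))

  # amyloid classification bookkeeping on baseline CSF values
  bl_csf <- cohort$data[cohort$data$outcome == "csf_ab42" &
                          cohort$data$visit_years == 0, ]
  ab_status <- classify_amyloid(bl_csf$value,
                                csf_threshold = config$csf_threshold,
                                borderline_frac = config$borderline_frac,
                                centiloid_threshold = config$centiloid_threshold)
  manifest$stages$amyloid <- as.list(table(ab_status))

  # ---- extract ----
  features <- stage("extract", {
    truth <- cohort$truth$subjects
    visits <- unique(cohort$data[, c("subject_id", "visit_years")])
    sev <- pipeline_severity(
      visits$visit_years +
        truth$shift_total[match(visits$subject_id, truth$subject_id)])
    rows <- vector("list", nrow(visits))
    for (r in seq_len(nrow(visits))) {
      sd_seed <- (config$seed + 7919L * r) %% .Machine$integer.max
      fl <- generate_phantom(severity_phantom_spec(sev[r], config$phantom_shape,
                                                   seed = sd_seed),
                             hemisphere = "left")
      fr <- generate_phantom(severity_phantom_spec(sev[r], config$phantom_shape,
                                                   seed = sd_seed + 1L),
                             hemisphere = "right")
      fv <- extract_all(fl, fr, n_bins = config$bins, trim_k = config$trim_k)
      rows[[r]] <- c(fv)
    }
    feat <- as.data.frame(do.call(rbind, rows))
    cbind(visits, feat)
  })
  write_table_csv(features, file.path(out_dir, "features.csv"))
  manifest$stages$extract <- list(n_sessions = nrow(features),
                                  n_features = ncol(features) - 2L)

  # ---- reduce ----
  reduced <- stage("reduce", {
    meta <- features[, c("subject_id", "visit_years")]
    fmat <- features[, setdiff(names(features),
                               c("subject_id", "visit_years", "volume"))]
    cl <- clean_features(fmat, iqr_mult = config$feature_iqr_mult)
    truth <- cohort$truth$subjects
    grp <- truth$group_bl[match(meta$subject_id, truth$subject_id)]
    train <- meta$visit_years == 0 & grp %in% c("CU-Ab-", "CU-Ab+") &
      stats::complete.cases(cl$table)
    model <- fit_pca(cl$table, train, retain_threshold = config$pca_retain)
    # excluded cells enter the projection at the training mean so sessions
    # with a few flagged cells keep usable component scores
    scores <- project_pca(model, cl$table, na_policy = "zero_impute")
    scores <- cbind(meta, scores, hv = features$volume)
    list(model = model, scores = scores, report = cl$report)
  })
  write_pca_json(reduced$model, file.path(out_dir, "pca.json"))
  write_table_csv(reduced$scores, file.path(out_dir, "scores.csv"))
  manifest$stages$reduce <- list(
    n_outlier_cells = reduced$report$n_outlier_cells,
    dropped_features = reduced$report$dropped_features,
    n_components = length(reduced$model$retained),
    variance_shares = unname(
      reduced$model$variance_explained[reduced$model$retained]))

  tx_cols <- grep("^txpc", names(reduced$scores), value = TRUE)

  # ---- crosssec ----
  crosssec <- stage("crosssec", {
    truth <- cohort$truth$subjects
    bl_meta <- unique(cohort$data[cohort$data$visit_years == 0,
                                  c("subject_id", "group_bl", "age_bl", "sex",
                                    "education", "icv", "site")])
    bl <- merge(bl_meta,
                reduced$scores[reduced$scores$visit_years == 0,
                               c("subject_id", tx_cols, "hv")],
                by = "subject_id")
    out <- list()
    pair_rows <- list()
    n_excluded <- 0L
    for (v in c(tx_cols, "hv")) {
      fl <- exclude_outliers(bl[[v]], iqr_mult = config$analysis_iqr_mult)$flags
      n_excluded <- n_excluded + sum(fl)
      sub <- bl[!fl, , drop = FALSE]
      gm <- fit_group_model(sub, v)
      out[[v]] <- list(anova = gm$anova, cohens_f = gm$cohens_f, n = gm$n)
      pc <- pairwise_contrasts(sub, v)
      pc$variable <- v
      pair_rows[[v]] <- pc
    }
    pairs <- do.call(rbind, pair_rows)
    pairs$p_adj <- adjust_pvalues(pairs$p)
    list(models = out, pairwise = pairs, n_excluded = n_excluded)
  })
  jsonlite::write_json(crosssec, file.path(out_dir, "crosssec.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$stages$crosssec <- list(n_outliers_excluded = crosssec$n_excluded,
                                   n_pairwise_tests = nrow(crosssec$pairwise))

  # ---- stage (latent disease time) ----
  staging <- stage("stage", {
    fit <- fit_progression(cohort$data,
                           outcomes = c("adas13", "cdrsb", "mmse", "centiloid"),
                           dof = config$progression_dof,
                           max_iter = config$progression_max_iter)
    staged <- predict_disease_time(fit, cohort$data)
    ab <- staged[staged$outcome == "csf_ab42", ]
    healthy <- ab$value[ab$group_bl == "CU-Ab-"]
    anchor <- anchor_time_zero(ab[, c("disease_time", "value")], healthy)
    fit <- apply_anchor(fit, anchor$offset)
    staged$disease_time <- staged$disease_time + anchor$offset
    list(fit = fit, staged = staged, anchor = anchor)
  })
  write_progression_json(staging$fit, file.path(out_dir, "progression.json"))
  write_table_csv(staging$staged, file.path(out_dir, "staged.csv"))
  manifest$stages$stage <- list(
    converged = staging$fit$converged,
    shift_sd = sqrt(staging$fit$shift_var),
    time_zero = staging$anchor$time_zero,
    disease_time_span = diff(range(staging$staged$disease_time)))

  # ---- trajectories ----
  traj <- stage("trajectories", {
    shifts <- attr(staging$staged, "shifts")
    sc <- reduced$scores
    j <- match(sc$subject_id, shifts$subject_id)
    sc$disease_time <- sc$visit_years + shifts$shift_total[j] +
      staging$fit$time_zero_offset
    truth <- cohort$truth$subjects
    sc$group_bl <- truth$group_bl[match(sc$subject_id, truth$subject_id)]
    sc$age_bl <- truth$age_bl[match(sc$subject_id, truth$subject_id)]
    fits <- list(); curves <- list(); duals <- list()
    for (v in c(tx_cols, "hv")) {
      dd <- data.frame(subject_id = sc$subject_id,
                       disease_time = sc$disease_time, value = sc[[v]],
                       age_bl = sc$age_bl, visit_years = sc$visit_years)
      tf <- fit_trajectory(dd, outcome = v,
                           dof_range = config$trajectory_dof_range,
                           trim = config$trajectory_trim)
      healthy <- sc[[v]][sc$group_bl == "CU-Ab-"]
      dir <- if (v == "hv") "decreasing" else "increasing"
      scale <- abnormality_scale(healthy[!is.na(healthy)], direction = dir)
      tgrid <- seq(tf$support[1], tf$support[2], length.out = 101)
      curves[[v]] <- data.frame(outcome = v, t = tgrid,
                                value = predict_trajectory(tf, tgrid),
                                abnormality = abnormality_curve(tf, scale, tgrid),
                                sensitivity = sensitivity_curve(tf, tgrid))
      duals[[v]] <- fit_dual_timescale(dd, outcome = v,
                                       dof_range = config$dual_dof_range)
      fits[[v]] <- tf
    }
    list(fits = fits, curves = do.call(rbind, curves), duals = duals)
  })
  write_table_csv(traj$curves, file.path(out_dir, "trajectory_curves.csv"))
  dual_tab <- do.call(rbind, lapply(traj$duals, function(d) {
    data.frame(outcome = d$outcome, form = d$form, dfd = d$dfd, dfa = d$dfa,
               bic = d$bic, stringsAsFactors = FALSE)
  }))
  write_table_csv(dual_tab, file.path(out_dir, "dual_selection.csv"))
  manifest$stages$trajectories <- list(
    selected_dof = vapply(traj$fits, `[[`, numeric(1), "dof"),
    dual_forms = vapply(traj$duals, `[[`, character(1), "form"))

  # ---- predict ----
  prediction <- stage("predict", {
    base_scores <- reduced$scores[reduced$scores$visit_years == 0, ]
    truth <- cohort$truth$subjects
    bl_meta <- unique(cohort$data[cohort$data$visit_years == 0,
                                  c("subject_id", "age_bl", "sex", "education",
                                    "icv")])
    predictors <- merge(bl_meta, base_scores[, c("subject_id", tx_cols, "hv")],
                        by = "subject_id")
    # pad texture columns to 5 for the nested-model interface
    for (i in seq_len(5)) {
      nm <- paste0("txpc", i)
      if (!nm %in% names(predictors)) predictors[[nm]] <- 0
    }
    res <- list()
    for (score in c("adas13", "cdrsb", "mmse")) {
      fr <- build_prediction_frame(cohort$data, predictors, score,
                                   horizon_months = config$horizon_months,
                                   window_months = config$window_months)
      res[[score]] <- compare_models(fr, n_boot = config$n_boot,
                                     seed = config$seed + match(score,
                                       c("adas13", "cdrsb", "mmse")))
    }
    res
  })
  jsonlite::write_json(
    lapply(prediction, function(r) list(summary = r$summary,
                                        comparisons = r$comparisons)),
    file.path(out_dir, "prediction.json"), auto_unbox = TRUE, digits = NA)
  manifest$stages$predict <- list(
    scores = names(prediction),
    n = vapply(prediction, `[[`, numeric(1), "n"))

  # ---- manifest with config hash ----
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config)[order(names(unclass(config)))],
                       cfg_path, auto_unbox = TRUE, digits = NA)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(cohort = cohort, features = features, reduced = reduced,
                 crosssec = crosssec, staging = staging, trajectories = traj,
                 prediction = prediction, manifest = manifest))
}
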