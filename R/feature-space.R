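#' Clean a feature table
#'
#' Applies the two exclusion rules used before feature reduction: cell
#' values further than `iqr_mult` interquartile ranges from the feature mean
#' are set missing (cells, not rows, are excluded), and features whose
#' variance (after cell exclusion) is below `var_tol` are dropped.
#'
#' @param table Data frame or matrix of numeric features (rows =
#'   subject-sessions).
#' @param iqr_mult IQR multiplier for the outlier fence (default 3).
#' @param var_tol Variance threshold below which a feature is dropped.
#' @return List with `table` (cleaned data frame) and `report`
#'   (`n_outlier_cells`, `dropped_features`).
#' @export
clean_features <- function(table, iqr_mult = 3, var_tol = 1e-10) {
  tab <- as.data.frame(table)
  if (nrow(tab) < 2L) stop("need at least 2 rows", call. = FALSE)
  stopifnot(all(vapply(tab, is.numeric, logical(1))))
  n_out <- 0L
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    m <- mean(v, na.rm = TRUE)
    iqr <- stats::IQR(v, na.rm = TRUE)
    bad <- !is.na(v) & abs(v - m) > iqr_mult * iqr
    if (iqr == 0) bad <- !is.na(v) & v != m
    n_out <- n_out + sum(bad)
    v[bad] <- NA_real_
    tab[[j]] <- v
  }
  vars <- vapply(tab, function(v) {
    if (sum(!is.na(v)) < 2L) 0 else stats::var(v, na.rm = TRUE)
  }, numeric(1))
  dropped <- names(tab)[vars < var_tol]
  tab <- tab[, vars >= var_tol, drop = FALSE]
  if (ncol(tab) == 0L) stop("all features dropped during cleaning", call. = FALSE)
  list(table = tab,
       report = list(n_outlier_cells = n_out, dropped_features = dropped))
}

#' Fit a PCA feature reduction on a training subset
#'
#' Z-scores features using means/SDs of the training rows only, computes the
#' principal axes from the training rows (the correlation structure, since
#' inputs are standardised) and retains components explaining at least
#' `retain_threshold` of total variance. Loading signs are fixed so each
#' component's largest-magnitude loading is positive, making outputs
#' reproducible across runs and platforms.
#'
#' @param table Cleaned numeric feature table.
#' @param training_rows Logical or integer selector of rows used to learn
#'   the standardisation and rotation (must be complete cases).
#' @param retain_threshold Minimum variance share for retention (default
#'   0.05).
#' @return Object of class `pca_model` with `means`, `sds`, `loadings`
#'   (all components), `variance_explained`, `retained`, `training_rows`.
#' @export
fit_pca <- function(table, training_rows, retain_threshold = 0.05) {
  tab <- as.data.frame(table)
  X <- as.matrix(tab[training_rows, , drop = FALSE])
  if (nrow(X) < 2L) stop("fewer than 2 training rows", call. = FALSE)
  if (anyNA(X)) stop("training rows must be complete cases", call. = FALSE)
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) {
    stop(sprintf("zero-variance training feature(s): %s",
                 paste(colnames(X)[sdev == 0], collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  L <- pc$rotation
  # deterministic sign convention
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  retained <- which(shares >= retain_threshold)
  if (length(retained) == 0L) stop("no components reach the retention threshold",
                                   call. = FALSE)
  structure(list(means = mu, sds = sdev, loadings = L,
                 variance_explained = shares, retained = retained,
                 retain_threshold = retain_threshold,
                 training_rows = training_rows),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d features, %d retained components (shares: %s)\n",
              length(x$means), length(x$retained),
              paste(sprintf("%.1f%%", 100 * x$variance_explained[x$retained]),
                    collapse = ", ")))
  invisible(x)
}

#' Project a feature table onto retained principal components
#'
#' Standardises rows with the training means/SDs and multiplies by the
#' retained loadings. Rows with missing cells get missing scores
#' (`na_policy = "propagate"`) or are scored on a best-effort basis by
#' zero-imputing standardised missing cells (`"zero_impute"`).
#'
#' @param model A [fit_pca()] model.
#' @param table Feature table containing the model's features.
#' @param na_policy `"propagate"` (default) or `"zero_impute"`.
#' @return Data frame of component scores, columns `txpc1`, `txpc2`, ...
#' @export
project_pca <- function(model, table, na_policy = c("propagate", "zero_impute")) {
  na_policy <- match.arg(na_policy)
  stopifnot(inherits(model, "pca_model"))
  tab <- as.data.frame(table)
  missing_cols <- setdiff(names(model$means), names(tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(tab[, names(model$means), drop = FALSE])
  Z <- sweep(sweep(X, 2, model$means), 2, model$sds, "/")
  incomplete <- rowSums(is.na(Z)) > 0L
  if (na_policy == "zero_impute") Z[is.na(Z)] <- 0
  S <- Z %*% model$loadings[, model$retained, drop = FALSE]
  if (na_policy == "propagate") S[incomplete, ] <- NA_real_
  S <- as.data.frame(S)
  names(S) <- paste0("txpc", seq_along(model$retained))
  S
}

#' Serialise a PCA model to JSON
#'
#' @param model A [fit_pca()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(model, path) {
  jsonlite::write_json(list(
    means = as.list(model$means), sds = as.list(model$sds),
    loadings = model$loadings, variance_explained = model$variance_explained,
    retained = model$retained, retain_threshold = model$retain_threshold
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
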