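# Clean the texture feature table (cells beyond mean +/- 3 IQR set missing,
# near-zero-variance features dropped) and reduce it by PCA. The rotation is
# learned only on baseline sessions of cognitively unimpaired subjects and
# applied to every session; components explaining >= 5% of training variance
# are retained as the texture scores (TxPC) used downstream.

source("analysis/00_config.R")

features <- read_table_csv(path_of("features.csv"))
truth <- read_table_csv(path_of("truth_synthetic.csv"))

meta <- features[, c("subject_id", "visit_years")]
fmat <- features[, setdiff(names(features),
                           c("subject_id", "visit_years", "volume"))]
cleaned <- clean_features(fmat, iqr_mult = cfg$feature_iqr_mult)

grp <- truth$group_bl[match(meta$subject_id, truth$subject_id)]
train <- meta$visit_years == 0 & grp %in% c("CU-Ab-", "CU-Ab+") &
  complete.cases(cleaned$table)
model <- fit_pca(cleaned$table, train, retain_threshold = cfg$pca_retain)
scores <- cbind(meta, project_pca(model, cleaned$table,
                                  na_policy = "zero_impute"),
                hv = features$volume)

write_pca_json(model, path_of("pca.json"))
write_table_csv(scores, path_of("scores.csv"))

cat(sprintf("Cleaning: %d outlier cells set missing, %d features dropped.\n",
            cleaned$report$n_outlier_cells,
            length(cleaned$report$dropped_features)))
cat(sprintf("PCA trained on %d baseline CU sessions; %d components retained\n",
            sum(train), length(model$retained)))
cat(sprintf("with variance shares %s.\n",
            paste(sprintf("%.0f%%",
                          100 * model$variance_explained[model$retained]),
                  collapse = ", ")))
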