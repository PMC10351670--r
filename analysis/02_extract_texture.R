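# Extract hippocampal-style texture from per-session 3D phantoms. Each
# subject-visit gets a left and right ROI phantom whose hyperintense
# clustering and size are driven by the subject's true latent disease time;
# both hemispheres run the full pipeline (mu +/- 3 sigma trimming,
# z-scoring, 32-bin discretisation, first-order + GLCM + GLRLM features,
# volume) and are averaged.

source("analysis/00_config.R")

cohort <- read_table_csv(path_of("cohort.csv"))
truth <- read_table_csv(path_of("truth_synthetic.csv"))

visits <- unique(cohort[, c("subject_id", "visit_years")])
sev <- pipeline_severity(
  visits$visit_years + truth$shift_total[match(visits$subject_id,
                                               truth$subject_id)])

rows <- vector("list", nrow(visits))
for (r in seq_len(nrow(visits))) {
  sd_seed <- (cfg$seed + 7919L * r) %% .Machine$integer.max
  left <- generate_phantom(
    severity_phantom_spec(sev[r], cfg$phantom_shape, seed = sd_seed), "left")
  right <- generate_phantom(
    severity_phantom_spec(sev[r], cfg$phantom_shape, seed = sd_seed + 1L),
    "right")
  rows[[r]] <- c(extract_all(left, right, n_bins = cfg$bins,
                             trim_k = cfg$trim_k))
}
features <- cbind(visits, as.data.frame(do.call(rbind, rows)))
write_table_csv(features, path_of("features.csv"))

cat(sprintf("Extracted %d features for %d sessions.\n",
            ncol(features) - 2L, nrow(features)))
cat(sprintf("Volume declines with severity: cor = %.2f.\n",
            cor(features$volume, sev)))
cat(sprintf("GLCM correlation (spatial coherence of the blobs) rises with severity: cor = %.2f.\n",
            cor(features$glcm_correlation, sev)))
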