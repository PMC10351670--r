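# Shared configuration for the numbered analysis drivers. Each driver can
# be run standalone from the repository root:
#   Rscript analysis/01_simulate.R
# Later drivers read the artifacts earlier ones wrote under results/.

library(hippotex)

cfg <- pipeline_config(
  n_per_group = 40,             # 160 subjects over the four baseline groups
  visit_schedule = c(0, 1, 2, 3),
  seed = 20260924L,
  n_boot = 200L,
  progression_max_iter = 300L
)
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

path_of <- function(...) file.path(results_dir, ...)
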