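#!/usr/bin/env Rscript
# Stage 5: feature-family comparison by rank-sum test on per-fold errors.
#
# For every ROI strategy, compares the fold RMSEs of voxel-pattern and
# lesion-load decoders (two-sided Wilcoxon rank-sum, exact for untied
# 10-vs-10 folds) and writes the comparison table.

suppressPackageStartupMessages(library(lesiondecode))

read_folds <- function(strategy, kind) {
  path <- file.path("results/model_grid",
                    sprintf("cv_%s_%s_gpr.tsv", strategy, kind))
  tab <- read.delim(path)
  as.numeric(tab$rmse[tab$fold != "mean"])
}

rows <- lapply(roi_strategies(), function(s) {
  a <- read_folds(s, "voxel_pattern")
  b <- read_folds(s, "lesion_load")
  w <- compare_models_wilcoxon(a, b)
  data.frame(mask_strategy = s,
             voxel_mean_rmse = mean(a), load_mean_rmse = mean(b),
             rank_sum_p = w$p_value, method = w$method)
})
tab <- do.call(rbind, rows)
dir.create("results/comparison", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/comparison/voxel_vs_load.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(cbind(tab[, 1, drop = FALSE],
            round(tab[, 2:4], 4), method = tab$method), row.names = FALSE)
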