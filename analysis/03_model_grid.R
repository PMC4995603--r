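#!/usr/bin/env Rscript
# Stage 3: the full decoding model grid.
#
# 8 ROI strategies x 2 feature families under GP regression, 10-fold
# cross-validation with all data-dependent steps (composite score, label
# scaling, problem-specific ROIs, feature standardization) confined to the
# training subjects of each fold. Per-fold tables, a summary table and the
# provenance record land in results/model_grid/.

suppressPackageStartupMessages(library(lesiondecode))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cfg_file <- tempfile(fileext = ".yaml")
writeLines(c(
  sprintf("seed: %d", seed),
  "input_dir: results/cohort",
  "output_dir: results/model_grid"
), cfg_file)

res <- run_experiment(load_config(cfg_file))
s <- res$summary[order(-res$summary$mean_r), ]
cat("model grid complete; ranked by mean cross-validated R:\n\n")
print(cbind(s[, c("mask_strategy", "feature_kind", "n_features")],
            mean_r = round(s$mean_r, 3), mean_rmse = round(s$mean_rmse, 3)),
      row.names = FALSE)
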