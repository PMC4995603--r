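#!/usr/bin/env Rscript
# Stage 4: region relevance by multiple kernel learning.
#
# One linear kernel per atlas structure (each region and each CST half is
# its own source, built from identically standardized voxel patterns);
# source weights learned by marginal-likelihood ascent on the full cohort,
# plus a cross-validated accuracy of the same model. The weight table is
# written sorted by descending relevance.

suppressPackageStartupMessages(library(lesiondecode))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

cohort <- read_cohort("results/cohort")
atlas <- cohort$atlas
n <- length(cohort$probs)

# cross-validated performance of the MKL decoder
cv <- run_cv(cohort, list(kind = "voxel_pattern",
                          mask_strategy = "atlas_plus_cst"),
             model_spec = list(kind = "mkl"),
             fold_plan = kfold_split(n, 10L, seed = seed), seed = seed)
cat(sprintf("MKL decoder: mean R = %.3f, mean RMSE = %.3f over %d folds\n",
            cv$mean_r, cv$mean_rmse, cv$n_folds_used))

# full-cohort relevance weights (descriptive, no held-out data)
seg <- lapply(cohort$probs, segment_lesion)
probs <- cohort$probs
for (i in seq_len(n)) {
  fl <- flip_to_right(probs[[i]], seg[[i]])
  probs[[i]] <- fl$prob
}
f <- fpc_scores(cohort$scores)
y <- (f$train - mean(f$train)) / sd(f$train)
mask <- build_strategy_mask("atlas_plus_cst", atlas)
X <- extract_voxel_patterns(probs, mask)
std <- standardize_features(X)$train
lab_of_col <- atlas$labels[attr(X, "voxel_index")]
groups <- split(seq_len(ncol(X)), lab_of_col)
names(groups) <- atlas$region_table$name[
  match(as.integer(names(groups)), atlas$region_table$label)]
sources <- lapply(groups, function(cc) tcrossprod(std[, cc, drop = FALSE]))
fit <- mkl_fit(sources, y, seed = seed)

tab <- weight_table(fit)
dir.create("results/mkl", recursive = TRUE, showWarnings = FALSE)
write.table(tab, "results/mkl/source_weights.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\ntop sources by relevance weight:\n")
print(head(tab, 8), row.names = FALSE)
cat("\nfull table: results/mkl/source_weights.tsv\n")
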