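#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# 50 subjects on a 32^3 grid (the desk-scale analogue of a full-resolution
# T1 volume), mirrored atlas with motor / non-motor / CST structures, soft
# ellipsoidal lesions of highly variable size, and four correlated motor
# scales driven by damage inside the motor regions. Everything is written
# under results/cohort/ as NIfTI + TSV so later stages (and any external
# tool) can pick it up.

suppressPackageStartupMessages(library(lesiondecode))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

out <- "results/cohort"
atlas <- make_atlas(c(32L, 32L, 32L), n_region_pairs = 10L, seed = seed)
motor <- atlas$region_table$label[atlas$region_table$category == "motor"]
cohort <- simulate_cohort(atlas, n_subjects = 50L, signal_regions = motor,
                          noise_sd = 0.1, beta_sd = 0.5, seed = seed)
cohort$functional_mask <- simulate_functional_mask(atlas)
write_cohort(cohort, out)

cat("cohort written to", out, "\n")
print(atlas)
cat("latent damage score range:",
    sprintf("%.3f .. %.3f", min(cohort$truth$latent_scores),
            max(cohort$truth$latent_scores)), "\n")
cat("score summaries:\n")
print(summary(cohort$scores[, -1]))
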