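#!/usr/bin/env Rscript

# Stage 1 -- simulate the replicate study.
#
# Generates HWE truth genotypes for six subjects and a full replicate study
# (6 subjects x 4 replicates x 5 experiments; E1-E3 on Affy6, E4-E5 on
# Illu1M). Per-experiment call-error rates are calibrated so the expected
# intra-experiment pair concordance 1 - 2e + 1.5e^2 matches the per-
# experiment averages the replicate literature reports (E1 99.04%, E2
# 99.48%, E3 99.69%, E4 99.90%, E5 99.85%). Six low-quality arrays are then
# injected: one heterozygosity-inflated replicate in E1 (subject F), one for
# each of subjects B, C, E, F in E2, plus one failed low-call-rate array in
# E2 (subject B, well H3).

suppressPackageStartupMessages(library(genorep))

seed <- 20120901L
n_snps <- 20000L
dir.create("results", showWarnings = FALSE)

## invert c = 1 - 2e + 1.5e^2 for the per-experiment error rate
rate_from_concordance <- function(c) (2 - sqrt(4 - 6 * (1 - c))) / 3
intra_target <- c(E1 = 0.9904, E2 = 0.9948, E3 = 0.9969,
                  E4 = 0.9990, E5 = 0.9985)
err <- vapply(intra_target, rate_from_concordance, numeric(1))
cat("calibrated per-experiment call-error rates:\n")
print(round(err, 5))

truth <- generate_truth(6L, n_snps, maf_low = 0.05, maf_high = 0.5,
                        seed = seed)
design <- reference_design()
model <- error_model(call_error_rate = err, nocall_rate = 0.005)
gm <- simulate_replicate_study(truth, design, model, seed = seed + 1L)

bad <- list(
  list(id = "F-2-E1", het = 0.10, drop = 0),
  list(id = "B-1-E2", het = 0.08, drop = 0),
  list(id = "C-2-E2", het = 0.12, drop = 0),
  list(id = "E-3-E2", het = 0.09, drop = 0),
  list(id = "F-4-E2", het = 0.11, drop = 0),
  list(id = "B-2-E2", het = 0.00, drop = 0.10)   # the well-H3 rescan failure
)
for (k in seq_along(bad)) {
  gm <- inject_low_quality(gm, bad[[k]]$id, het_inflation = bad[[k]]$het,
                           callrate_drop = bad[[k]]$drop,
                           seed = seed + 10L + k)
}

write_genotype_tsv(gm, "results/calls.tsv")
write_design_tsv(design, "results/design.tsv")
cat(sprintf("wrote results/calls.tsv (%d samples x %d SNPs) and results/design.tsv\n",
            nrow(gm$calls), ncol(gm$calls)))
cat("injected low-quality arrays:",
    paste(vapply(bad, `[[`, "", "id"), collapse = ", "), "\n")
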