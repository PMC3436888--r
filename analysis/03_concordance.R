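#!/usr/bin/env Rscript

# Stage 3 -- reproducibility of genotypes between technical replicates.
#
# On the QC-retained arrays, computes every same-subject pairwise genotype
# concordance (co-called denominator) and aggregates it at the three
# comparison levels: intra-experiment, inter-laboratory (same platform,
# different experiments) and inter-platform. Also writes the per-experiment
# replicate concordance matrices (the numeric content of the heatmaps).

suppressPackageStartupMessages(library(genorep))

gm <- read_genotype_tsv("results/calls.tsv")
design <- read_design_tsv("results/design.tsv")
flags <- data.table::fread("results/qc_flags.tsv")
keep <- design[!design$sample_id %in% flags$sample_id, , drop = FALSE]

pairs <- concordance_pairs(gm, keep, mode = "co_called")
data.table::fwrite(pairs, "results/pairs.tsv", sep = "\t")

summaries <- do.call(rbind, lapply(
  c("intra", "inter_lab", "inter_platform"),
  function(lv) summarize_reproducibility(pairs, lv)))
data.table::fwrite(summaries, "results/summaries.tsv", sep = "\t")

overall <- subset(summaries, subject == "ALL")
cat("overall reproducibility (co-called, QC-retained arrays):\n")
print(transform(overall[, c("level", "mean_concordance", "sd_concordance",
                            "n_pairs")],
                mean_concordance = sprintf("%.2f%%", 100 * mean_concordance),
                sd_concordance = sprintf("%.2f%%", 100 * sd_concordance)),
      row.names = FALSE)

for (ex in paste0("E", 1:5)) {
  ids <- keep$sample_id[keep$experiment_id == ex]
  mat <- concordance_matrix(gm, samples = ids, mode = "co_called")
  write_matrix_tsv(mat, sprintf("results/concordance_%s.tsv", ex))
}
cat("wrote results/pairs.tsv, results/summaries.tsv and per-experiment matrices\n")
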