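#!/usr/bin/env Rscript
# Univariate screening: per feature, two-sided Mann-Whitney U between the
# growth groups over the pooled weekly samples, Benjamini-Hochberg FDR per
# block, and median (P25-P75) group summaries.

library(lactomics)

out_dir <- "results/study"
blocks <- c("metabolome_pos", "metabolome_neg", "lipidome", "glycome",
            "faa", "fa")
meta <- read.csv("results/study/data/samples.csv", stringsAsFactors = FALSE)
bio <- meta[!meta$is_qc, ]

for (b in blocks) {
  tab <- suppressMessages(read_feature_table(
    file.path(out_dir, paste0("filtered_", b, ".csv")), b))
  if (b == "glycome")
    tab <- relative_hmo_abundance(
      feature_table(b, tab$values[bio$sample_id, , drop = FALSE]))
  res <- univariate_screen(tab, meta)
  write.csv(res, file.path(out_dir, paste0("univariate_", b, ".csv")),
            row.names = FALSE)
  cat(sprintf("%-14s %3d features: %2d with MW q < 0.05, %2d trends (q < 0.1)\n",
              b, nrow(res), sum(res$q < 0.05), sum(res$q >= 0.05 & res$q < 0.1)))
}
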