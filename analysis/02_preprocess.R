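#!/usr/bin/env Rscript
# Quality control and preprocessing: drop features whose pooled-QC relative
# SD exceeds 30%, convert the glycome to relative abundances, and classify
# maternal secretor status from milk 2'-FL.

library(lactomics)

data_dir <- "results/study/data"
out_dir <- "results/study"
blocks <- c("metabolome_pos", "metabolome_neg", "lipidome", "glycome",
            "faa", "fa")
meta <- read.csv(file.path(data_dir, "samples.csv"), stringsAsFactors = FALSE)
validate_cohort_metadata(meta)

for (b in blocks) {
  tab <- suppressMessages(read_feature_table(
    file.path(data_dir, paste0(b, ".csv")), b,
    feature_meta = file.path(data_dir, paste0("features_", b, ".csv"))))
  filt <- suppressMessages(qc_rsd_filter(tab, meta, cutoff = 0.30))
  write_feature_table(filt, file.path(out_dir, paste0("filtered_", b, ".csv")))
  cat(sprintf("%-14s %3d -> %3d features after 30%% QC-RSD filter\n",
              b, ncol(tab$values), ncol(filt$values)))
}

bio <- meta[!meta$is_qc, ]
gly <- suppressMessages(read_feature_table(
  file.path(out_dir, "filtered_glycome.csv"), "glycome"))
rel <- relative_hmo_abundance(
  feature_table("glycome", gly$values[bio$sample_id, , drop = FALSE]))
status <- classify_secretor(rel, meta)
write.csv(data.frame(mother_id = names(status), secretor = unname(status)),
          file.path(out_dir, "secretor_status.csv"), row.names = FALSE)
cat(sprintf("secretor classification: %d secretor, %d non-secretor mothers\n",
            sum(status == "secretor"), sum(status == "non-secretor")))
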