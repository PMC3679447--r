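#!/usr/bin/env Rscript
# Simulate the study's small-RNA libraries: a synthetic reference panel
# (TE consensus set, flamenco-like uni-strand cluster, 42AB-like
# dual-strand cluster, miRNA anchors) and matched control/knockdown
# library pairs for three emulated type I biogenesis-factor knockdowns
# (primary-pathway output reduced to 25%, 20% and 23%).
# Writes FASTA/FASTQ/BED/JSON under results/data/.

suppressPackageStartupMessages(library(pirnakit))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924L

reductions <- c(gasz_like = 0.25, zuc_like = 0.20, armi_like = 0.23)

base_cfg <- function(r, seed) {
  sim_config(n_te = 8L, te_length_range = c(600L, 1000L),
             n_mirna = 20L, pingpong_sites = 200L,
             pingpong_fraction = c(te01 = 0.5, te02 = 0.5),
             primary_reduction = r, library_depth = 50000L,
             seed = seed)
}

cfg0 <- base_cfg(1, seed)
ref <- build_reference(cfg0)
write_reference(ref, file.path(out, "reference.fa"),
                file.path(out, "cluster_fragments.bed"),
                file.path(out, "class_map.tsv"))
cat("reference:", nrow(ref$features), "features;",
    sum(ref$features$class == "TE"), "TEs,",
    sum(ref$features$class == "cluster"), "clusters,",
    sum(ref$features$class == "miRNA"), "miRNAs\n")

for (kd in names(reductions)) {
  cfg <- base_cfg(reductions[[kd]], seed)
  pair <- simulate_knockdown_pair(ref, cfg)
  write_reads(pair$control, file.path(out, sprintf("%s_control.fq", kd)),
              "fastq")
  write_reads(pair$knockdown, file.path(out, sprintf("%s_kd.fq", kd)),
              "fastq")
  write_truth(pair$truth, file.path(out, sprintf("%s_truth.json", kd)))
  cat(sprintf("%s: control %d reads, knockdown %d reads (r = %.2f)\n",
              kd, sum(pair$control$count), sum(pair$knockdown$count),
              reductions[[kd]]))
}
cat("done; libraries under", out, "\n")
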