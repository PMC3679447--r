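#!/usr/bin/env Rscript
# Map the simulated libraries back onto the reference panel, normalize
# each to its miRNA content (reads per million miRNA-mapped reads), and
# tabulate per-class weighted counts and length histograms.
# Requires analysis/01_simulate_libraries.R to have run.

suppressPackageStartupMessages(library(pirnakit))

dat <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- load_annotations(file.path(dat, "reference.fa"),
                        file.path(dat, "cluster_fragments.bed"),
                        file.path(dat, "class_map.tsv"))

libs <- list.files(dat, pattern = "\\.fq$")
summary_rows <- list()
for (f in libs) {
  name <- sub("\\.fq$", "", f)
  reads <- read_sequences(file.path(dat, f), "fastq")
  al <- map_reads(reads, ref)
  lib <- normalize_library(al, ref)
  cc <- class_counts(al, ref)
  lh <- length_histogram(lib)
  write.table(lh, file.path(out, sprintf("length_hist_%s.tsv", name)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_rows[[name]] <- data.frame(
    library = name, total_reads = sum(reads$count),
    mirna = cc$by_class[["miRNA"]], te = cc$by_class[["TE"]],
    cluster = cc$by_class[["cluster"]],
    mirna_total = lib$mirna_total, factor = lib$factor)
  cat(sprintf("%-18s %6d reads, miRNA anchor %.0f, factor %.1f\n",
              name, sum(reads$count), lib$mirna_total, lib$factor))
}
tab <- do.call(rbind, summary_rows)
write.table(tab, file.path(out, "library_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "library_summary.tsv"), "\n")
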