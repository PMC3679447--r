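#!/usr/bin/env Rscript
# Ping-pong and nucleotide-bias signatures across a grid of ping-pong
# fractions: the 5'-overlap histogram with its bin-10 z-score, and the
# position-10 adenosine content of sense TE piRNAs against its
# background expectation (positions 2-9 and 11-23).

suppressPackageStartupMessages(library(pirnakit))

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924L

rows <- list()
hist_rows <- list()
for (phi in c(0, 0.2, 0.5)) {
  cfg <- sim_config(n_te = 4L, te_length_range = c(500L, 900L),
                    n_mirna = 20L, pingpong_fraction = phi,
                    library_depth = 50000L, seed = seed + round(100 * phi))
  ref <- build_reference(cfg)
  lib <- normalize_library(map_reads(simulate_library(ref, cfg)$reads,
                                     ref), ref)
  h <- overlap_histogram(lib)
  b <- positional_bias(lib)
  rows[[length(rows) + 1L]] <- data.frame(
    phi = phi, z10 = h$z10, significant = h$significant,
    bin10_fraction = h$fraction[10],
    a10_observed = b$observed, a10_expected = b$expected,
    a10_excess = b$excess)
  hist_rows[[length(hist_rows) + 1L]] <- data.frame(
    phi = phi, overlap = seq_along(h$fraction), fraction = h$fraction)
  cat(sprintf(
    "phi %.1f: z10 %6.1f (%ssignificant), 10A %.3f vs expected %.3f\n",
    phi, h$z10, if (h$significant) "" else "not ", b$observed,
    b$expected))
}
write.table(do.call(rbind, rows), file.path(out, "signature_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, hist_rows),
            file.path(out, "overlap_histograms.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("ping-pong appears as a sharp 10 nt overlap peak and a 10A excess;",
    "both vanish at phi = 0\n")
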