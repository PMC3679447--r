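# pirnakit

Small-RNA analytics for the Drosophila piRNA pathway — the silencing
system in which PIWI-bound 23–30 nt piRNAs, produced from
transposon-rich clusters and amplified by the ping-pong cycle, keep
transposable elements (TEs) repressed in the ovary. The package is
aimed at analysts who need the standard library-level piRNA statistics
on consensus/cluster panels, and at method developers who want a fully
seeded synthetic testbed with ground truth.

It provides, end to end:

* a **generative simulator** of piRNA/miRNA sequencing libraries with
  ground truth: uni-strand (flamenco-like) and dual-strand (42AB-like)
  clusters assembled from TE fragments, 1U-biased primary piRNAs,
  ping-pong read pairs with exact 10 nt 5′ overlaps (so a 1U initiator
  forces a 10A responder), an invariant miRNA anchor population, and
  knockdown perturbations that multiply primary-pathway output by a
  factor *r*;
* **IO and mapping**: FASTA/FASTQ read collapsing, BED/class-map
  reference panels, and an exact strand-aware mapper with multi-mapper
  weighting (`weight = count / n_hits`);
* **normalization and profiles**: reads per million miRNA-mapped reads
  (RPMM), signed sense/antisense 5′-end coverage profiles, length
  histograms, RPKM tables with an expression cutoff;
* **signatures**: the ping-pong 5′-overlap histogram with its bin-10
  z-score `z10 = (f10 − mean(f≠10)) / sd(f≠10)`, and positional
  nucleotide bias (e.g. 10A content of sense TE piRNAs against the
  average over positions 2–9 and 11–23);
* **knockdown comparison**: per-TE antisense levels, log2 fold changes,
  Pearson correlation across all TEs, the global 23–30 nt piRNA
  reduction ratio, and type-I biogenesis-factor labels
  (collapsed / pingpong-rescued / unchanged);
* **RNAi screen statistics**: hit-rate arithmetic, the per-line
  efficiency → gene-level false-negative model `fn(n) = (1 − p)^n`,
  expression-bin phenotype rates, fold-change group box statistics with
  Wilcoxon rank tests, and two-reporter soma/germline specificity
  classes.

## Worked example

Simulate a control/knockdown pair emulating a type I biogenesis-factor
knockdown (primary pathway reduced to 25%, ping-pong active on 2 of 8
TEs), then run the whole analysis chain:

```r
library(pirnakit)

cfg <- sim_config(n_te = 8L, te_length_range = c(600L, 1000L),
                  n_mirna = 20L, pingpong_sites = 200L,
                  pingpong_fraction = c(te01 = 0.5, te02 = 0.5),
                  primary_reduction = 0.25, library_depth = 50000L,
                  seed = 1L)
wf <- run_knockdown_workflow(cfg)

wf$control
#> normalized_library: 29327 alignments, miRNA total 12401.0, factor 80.64, piRNA window [23, 30]
sprintf("global ratio %.3f", wf$report$global_ratio)
#> [1] "global ratio 0.321"
sprintf("pearson r %.3f", wf$report$pearson_r)
#> [1] "pearson r 0.971"
unlist(wf$report$pingpong_z10)
#>   control knockdown
#>      16.9      28.1
table(wf$typeI)
#>        collapsed pingpong-rescued        unchanged
#>                5                2                1
```

Reading the numbers: the miRNA-normalized 23–30 nt piRNA mass of the
knockdown drops to ~32% of control — above the configured 25% because
the ping-pong arm of the two high-φ TEs persists. The per-TE scatter
stays highly correlated (r ≈ 0.97), the pooled ping-pong z-score rises
from 16.9 to 28.1 as the primary background collapses, and the type-I
labels recover the design: the two ping-pong TEs are
"pingpong-rescued", most others collapse.

The numbered drivers under `analysis/` run the same chain as a
narrative workflow — `01_simulate_libraries.R` writes FASTQ/BED/truth
JSON under `results/data/`, `02`–`04` map, normalize, score signatures
and compare knockdowns, `05_screen_statistics.R` computes the screen
arithmetic — each writing tables under `results/tables/`.

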