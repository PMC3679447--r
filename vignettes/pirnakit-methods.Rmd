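---
title: "Methods: simulating and scoring piRNA pathway small-RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring piRNA pathway small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

## Scope and model

`pirnakit` analyses small-RNA sequencing libraries from systems with an
active piRNA pathway, with the Drosophila ovary as the motivating case.
Its statistics target the quantities that characterise piRNA biology at
the library level:

* **miRNA-anchored normalization.** piRNA-pathway perturbations change
  piRNA abundance but not miRNA abundance, so libraries are expressed in
  reads per million miRNA-mapped reads (RPMM). The factor is
  $10^6 / m$ where $m$ is the weighted miRNA-mapped count; it fails
  loudly when no miRNA anchor is present.
* **Ping-pong signature.** For every feature, each (sense $s$, antisense
  $a$) pair of piRNA-window alignments contributes the product of its
  weights to overlap bin $o = \mathrm{fp}(a) - \mathrm{fp}(s) + 1$,
  where $\mathrm{fp}$ is the strand-aware 5' coordinate. Ping-pong
  amplification creates pairs at exactly $o = 10$. The score is
  $z_{10} = (f_{10} - \bar f_{\neq 10}) / s_{\neq 10}$ over bins 1–25,
  with the sample standard deviation; the significance call defaults to
  $z_{10} \ge 3$. The threshold is a package default: published displays
  of this statistic mark significance without defining it numerically.
* **Positional bias (1U/10A).** Primary piRNAs are uridine-biased at
  position 1; ping-pong responders are adenosine-biased at position 10
  because position 10 pairs with the initiator's first base. Observed
  content at a position is compared with the mean content over
  background positions 2–9 and 11–23 of the same reads.
* **Knockdown comparison.** Per-TE antisense RPMM levels, log2 fold
  changes with a pseudocount (default 1 RPMM), Pearson correlation of
  the log2 level vectors across all TEs, the global 23–30 nt non-miRNA
  RPMM ratio (the "piRNA populations reduced to X%" statistic), and the
  per-TE change in $z_{10}$.
* **Screen statistics.** Gene-level hit rates from per-line staining
  records, the false-negative model $\mathrm{fn}(n) = (1-p)^n$ for
  per-line efficiency $p$ and $n$ lines per gene, expression-bin
  phenotype rates, box statistics with Wilcoxon rank tests for
  fold-change groups, and two-reporter (soma/germline) specificity
  classes.

## The generative simulator

Because the underlying fly and OSC libraries are not redistributable at
desk scale, every pipeline stage is exercised against a seeded
generative model (`sim_config()`, `build_reference()`,
`simulate_library()`, `simulate_knockdown_pair()`) that emulates the
biogenesis logic:

* **Reference panel.** Random TE consensus sequences (default 6–8 TEs of
  0.6–1.5 kb), a uni-strand cluster whose fragments are all
  reverse-complemented TE copies (flamenco-like, so cluster-derived
  piRNAs are antisense to their TEs), a dual-strand cluster with random
  fragment orientation (42AB-like), and an invariant miRNA panel
  (default 40 species of 22 nt).
* **Primary piRNAs** are exact substrings of cluster transcripts (sense)
  or antisense-TE transcripts. 5' positions are uniform over the
  eligible transcript — the source publications show dispersed profiles
  and give no positional model. Lengths are discrete truncated normal
  (mean 26 nt, sd 1.5, window 23–30 nt).
* **1U bias** is an exact Bernoulli($\beta$) mixture: with probability
  $\beta$ the 5' position is drawn from U-start positions, otherwise
  from non-U starts. A pure accept/reject scheme would converge to
  $\beta + (1-\beta)\,p_{bg}$ rather than $\beta$; the mixture keeps the
  observed 1U fraction equal to $\beta$ (the package's bias law) while
  reads remain exact reference substrings, so the exact matcher still
  places every simulated read.
* **Ping-pong pairs.** For TEs with ping-pong fraction $\phi_t > 0$,
  discrete pair sites are drawn once per library composition; each pair
  emits an antisense initiator with 5' at site $a$ and a sense responder
  with 5' at $a - 9$, giving exactly a 10 nt 5' overlap. Because both
  reads are exact substrings, the responder's position 10 equals the
  TE base under the initiator's first position: a 1U initiator forces a
  10A responder, and the simulated responder-10A fraction equals the
  initiator-1U fraction identically. Site usage rates are mildly
  dispersed (log-normal, sd 0.4 on the log scale); an earlier
  heavier-tailed choice concentrated pair mass on few sites and made
  per-TE $z_{10}$ values fluctuate strongly between seeds.
* **Knockdowns.** A control/knockdown pair shares one composition draw;
  the knockdown multiplies all primary-pathway expectations (cluster
  transcripts and the antisense-TE primary arm) by $r \in [0,1]$ before
  Poisson sampling. miRNA expectations are identical in both libraries
  and ping-pong pair expectations are unscaled, which reproduces the
  type-I phenotype: most TEs collapse while high-$\phi$ TEs retain
  their levels with a strengthened overlap signature. Because the
  ping-pong arm is unscaled, the global 23–30 nt ratio equals $r$
  exactly only in $\phi = 0$ configurations; parameter-recovery checks
  therefore run with $\phi = 0$.
* **Determinism.** All draws derive from `config$seed` (reference at
  the seed itself, composition at +1, control sampling at +2, knockdown
  at +3); identical configurations reproduce byte-identical FASTQ and
  truth JSON.

What the simulator does **not** model: sequencing error, adapter
artefacts, secondary structure, Hen1 2'-O-methylation, trailer
trimming, genomic background outside the annotated panel, and mismatched
mapping. Consequently, passing tests demonstrate the correctness of the
statistics on clean exact-match data, not robustness to the noise
sources of real libraries.

## Mapping and weighting

`map_reads()` is exact (0 mismatches) and strand-aware. References here
are consensus/cluster panels of at most a few megabases, so the matcher
scans every length-$L$ window of the N-spacered concatenated panel and
hash-joins windows against the collapsed read sequences of that length,
on both strands — no index structure, and exactness keeps the
brute-force oracle trivial. Minus-strand hits store the feature
coordinate of the biological 5' nucleotide (the right end of the
match); this is what makes the overlap arithmetic above exact. A read's
count is split evenly over its hits (`weight = count / n_hits`), reads
with more than `max_hits` (default 100) hits are discarded and logged,
and multi-class reads contribute weight proportionally to each class.

## Numerical choices and degenerate inputs

* Overlap bins run 1–25; pair weighting is the product of alignment
  weights (bilinear, oracle-checkable), not min or binary.
* $z_{10}$ degenerate cases: zero total mass, or zero background sd
  with $f_{10}$ at the background mean, give $z_{10} = 0$ (not
  significant); zero sd with $f_{10}$ above the mean yields the
  $+\infty$ sentinel (significant).
* Positional bias with no qualifying reads is flagged undefined
  (`defined = FALSE`), never silently 0.
* RPKM is `count / (length/1e3) / (total/1e6)`; the expression cutoff
  comparison is inclusive (`>=`), and the expression-bin tool assigns
  the integer-division remainder to the top bin.
* Coverage profiles record 5'-end mass only (the quantity entering the
  overlap statistic), as a two-column (sense, antisense) signed matrix
  so strand masses never cancel at shared positions; full-read coverage
  is intentionally out of scope.
* The log2 pseudocount default is 1 RPMM; TE-origin classification uses
  a 1-log2-unit margin; type-I labels use `fc_threshold = 2` and
  `dz_threshold = 2`. All are documented defaults, not published
  constants, and are exposed as arguments.
* The screen staining scale is the ordinal 0–5 labelling `none` …
  `strong`; the "strong range" defaults to `intermediate-strong` and
  `strong`. The fold-change group test defaults to the unpaired
  two-sided Wilcoxon rank-sum test (groups compare different RNAi
  lines); a `paired` argument covers matched designs.
* The gene-level detection model assumes line independence; both the
  model value $(1-p)^n$ and the empirical per-gene miss rate are
  reported, since published summary figures mix the two views.

## Problem sizes in the test and acceptance suites

The bundled suites run at desk scale, chosen as the package's own study
conditions: mapper oracle on 50 references up to 2 kb with 500 reads;
ping-pong null calibration over 100 seeds at depth 20,000 with
$\phi = 0$; signal detection over 20 seeds at depth 50,000 with
$\phi = 0.5$; reduction-factor recovery over 20 seeds per
$r \in \{0.1, 0.25, 0.5, 1\}$ at depth 30,000; bias-law monotonicity
over $\phi \in \{0, 0.3, 0.6\}$ at fixed seed sets. Statistical
assertions use 3-standard-error (or binomial-SE) bands around the
generative truth.

## Known limitations

* Per-TE $\Delta z_{10}$ retains seed-to-seed noise of a few z units
  even at depth $10^5$: background bins of a per-TE histogram hold
  little mass, so their sample sd is unstable. The type-I classifier is
  therefore exact as a rule but marginal calls near
  `dz_threshold` flip between replicates; pooled (all-TE) $z_{10}$ is
  far more stable.
* Exact matching understates multi-mapping relative to a
  mismatch-tolerant mapper; cluster-derived reads split weight with
  their source TEs by construction.
* The RPKM module is table-driven and knows nothing of gene models or
  exon unions; it computes the statistic on supplied counts and
  lengths.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(primary_reduction = 0.25, seed = 1L)
wf <- run_knockdown_workflow(cfg)
wf$report$global_ratio    # ~0.25-0.35 depending on phi
wf$report$pingpong_z10
typeI_signature(wf$comparison)
```
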