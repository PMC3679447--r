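# Minimal normalized library around explicit alignment rows on one TE.
sig_library <- function(rows) {
  ref <- reference_set(
    Biostrings::DNAStringSet(c(te1 = strrep("ACGT", 50),
                               mir1 = strrep("C", 22))),
    data.frame(id = c("te1", "mir1"), class = c("TE", "miRNA"),
               length = c(200L, 22L), stringsAsFactors = FALSE))
  base <- data.frame(read_id = "m0", feature_id = "mir1", strand = "+",
                     five_prime = 0L, length = 22L, weight = 1e6,
                     unique = TRUE, stringsAsFactors = FALSE)
  normalize_library(rbind(base, rows), ref)
}

sig_row <- function(id, strand, fp, w, len = 26L) {
  data.frame(read_id = id, feature_id = "te1", strand = strand,
             five_prime = as.integer(fp), length = len, weight = w,
             unique = TRUE, stringsAsFactors = FALSE)
}

test_that("overlap arithmetic: pair masses land in the stated bins", {
  # sense 5' 0 (w 2) + antisense 5' 9 (w 3): o = 10, mass 6
  lib <- sig_library(rbind(sig_row("s", "+", 0, 2),
                           sig_row("a", "-", 9, 3)))
  h <- overlap_histogram(lib, "te1")
  expect_equal(h$mass[10], 6)
  expect_equal(sum(h$mass), 6)
  # sense 5' 0 + antisense 5' 4: o = 5
  lib2 <- sig_library(rbind(sig_row("s", "+", 0, 2),
                            sig_row("a", "-", 4, 3)))
  expect_equal(overlap_histogram(lib2, "te1")$mass[5], 6)
  # opposite-strand pairs absent: zero histogram, not significant
  lib3 <- sig_library(sig_row("s", "+", 0, 2))
  h3 <- overlap_histogram(lib3, "te1")
  expect_equal(sum(h3$mass), 0)
  expect_false(h3$significant)
})

test_that("overlap histogram equals the all-pairs double loop oracle", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 60
    rows <- do.call(rbind, lapply(seq_len(n), function(i)
      sig_row(sprintf("r%03d", i), sample(c("+", "-"), 1),
              sample(0:180, 1), runif(1, 0.2, 3),
              len = sample(23:30, 1))))
    lib <- sig_library(rows)
    h <- overlap_histogram(lib, "te1")
    bf <- brute_force_overlap(lib$alignments[-1, ], lib$ref)
    expect_equal(h$mass, bf, tolerance = 1e-12)
  }
})

test_that("relabeling strands (reverse-complement view) keeps bin masses", {
  set.seed(103)
  rows <- do.call(rbind, lapply(1:40, function(i)
    sig_row(sprintf("r%03d", i), sample(c("+", "-"), 1),
            sample(0:180, 1), runif(1, 0.2, 3), len = sample(23:30, 1))))
  lib <- sig_library(rows)
  h <- overlap_histogram(lib, "te1")
  # view the feature from the opposite strand: position x -> L-1-x,
  # strands swap
  len <- 200L
  flipped <- rows
  flipped$strand <- ifelse(rows$strand == "+", "-", "+")
  flipped$five_prime <- len - 1L - rows$five_prime
  lib2 <- sig_library(flipped)
  h2 <- overlap_histogram(lib2, "te1")
  expect_equal(h2$mass, h$mass, tolerance = 1e-12)
})

test_that("z-score matches an independent mean/sd recomputation", {
  mass <- c(rep(0.0158, 9), 0.62, rep(0.0158, 15))
  z <- pingpong_z(mass)
  f <- mass / sum(mass)
  z_manual <- (f[10] - mean(f[-10])) / sd(f[-10])
  expect_equal(z$z10, z_manual)
  expect_true(z$significant)
  # flat histogram: z = 0, not significant
  zf <- pingpong_z(rep(1, 25))
  expect_equal(zf$z10, 0)
  expect_false(zf$significant)
  # degenerate: only bin 10 occupied -> +Inf sentinel
  only10 <- c(rep(0, 9), 1, rep(0, 15))
  zs <- pingpong_z(only10)
  expect_identical(zs$z10, Inf)
  expect_true(zs$significant)
})

test_that("ping-pong signal is detected and the null is quiet", {
  cfg0 <- small_config(seed = 111L, phi = 0, depth = 20000L)
  ref <- build_reference(cfg0)
  hits <- 0L
  for (seed in 1:8) {
    c1 <- cfg0; c1$seed <- 200L + seed
    lib <- normalize_from_reads(simulate_library(ref, c1)$reads, ref)
    if (overlap_histogram(lib)$significant) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
  cfgs <- small_config(seed = 111L, phi = 0.5, depth = 20000L)
  for (seed in 1:3) {
    c1 <- cfgs; c1$seed <- 300L + seed
    lib <- normalize_from_reads(simulate_library(ref, c1)$reads, ref)
    h <- overlap_histogram(lib)
    expect_true(h$significant)
    expect_equal(which.max(h$mass), 10L)
  }
})

test_that("positional bias follows the direct count definition", {
  # two equal-weight 23 nt sense reads: one with A only at position 10,
  # one A-free -> observed 0.5, expected 0
  ref <- reference_set(
    Biostrings::DNAStringSet(c(te1 = strrep("ACGT", 50),
                               mir1 = strrep("C", 22))),
    data.frame(id = c("te1", "mir1"), class = c("TE", "miRNA"),
               length = c(200L, 22L), stringsAsFactors = FALSE))
  r1 <- paste0(strrep("C", 9), "A", strrep("C", 13))  # A at pos 10 only
  r2 <- strrep("G", 23)                               # A-free
  al <- rbind(
    data.frame(read_id = "m0", feature_id = "mir1", strand = "+",
               five_prime = 0L, length = 22L, weight = 1e6, unique = TRUE),
    data.frame(read_id = c("r1", "r2"), feature_id = "te1",
               strand = "+", five_prime = c(0L, 30L), length = 23L,
               weight = 1, unique = TRUE))
  reads <- data.frame(read_id = c("m0", "r1", "r2"),
                      sequence = c(strrep("C", 22), r1, r2),
                      count = 1L, stringsAsFactors = FALSE)
  attr(al, "reads") <- reads
  lib <- normalize_library(al, ref)
  b <- positional_bias(lib)
  expect_equal(b$observed, 0.5)
  expect_equal(b$expected, 0)
  expect_equal(b$excess, 0.5)

  # all-A reads: observed = expected = 1
  reads$sequence[2:3] <- strrep("A", 23)
  attr(al, "reads") <- reads
  libA <- normalize_library(al, ref)
  bA <- positional_bias(libA)
  expect_equal(bA$observed, 1)
  expect_equal(bA$expected, 1)
  expect_equal(bA$excess, 0)

  # no qualifying reads: flagged undefined, not zero
  al0 <- al[1, , drop = FALSE]
  attr(al0, "reads") <- reads[1, , drop = FALSE]
  b0 <- positional_bias(normalize_library(al0, ref))
  expect_false(b0$defined)
  expect_true(is.na(b0$observed))
})

test_that("expected 10A level equals the background-position recount", {
  cfg <- small_config(seed = 121L, phi = 0.4, depth = 15000L)
  ref <- build_reference(cfg)
  lib <- normalize_from_reads(simulate_library(ref, cfg)$reads, ref)
  b <- positional_bias(lib)
  # independent recount of the expected line over positions 2-9, 11-23
  reads <- attr(lib$alignments, "reads")
  al <- lib$alignments
  cls <- lib$ref$features$class[match(al$feature_id, lib$ref$features$id)]
  al <- al[cls == "TE" & al$strand == "+" &
           al$length >= 23 & al$length <= 30, ]
  seqs <- reads$sequence[match(al$read_id, reads$read_id)]
  fr <- vapply(c(2:9, 11:23), function(p) {
    ok <- nchar(seqs) >= p
    sum(al$weight[ok] * (substring(seqs[ok], p, p) == "A")) /
      sum(al$weight[ok])
  }, numeric(1))
  expect_equal(b$expected, mean(fr))
})
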