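# Shared fixtures: small configurations and independent oracles.

# Small TE-only panel (no clusters): class masses are unambiguous because
# random TEs share no 18+ nt substrings.
te_only_config <- function(seed, depth = 20000L, phi = 0, n_te = 4L,
                           u1_bias = 0.9) {
  sim_config(n_te = n_te, te_length_range = c(400L, 800L),
             cluster_spec = list(), n_mirna = 20L,
             pingpong_fraction = phi, u1_bias = u1_bias,
             library_depth = as.integer(depth), seed = as.integer(seed))
}

# Default-shaped small panel with both cluster types.
small_config <- function(seed, depth = 20000L, phi = 0.2, ...) {
  sim_config(n_te = 4L, te_length_range = c(500L, 900L),
             n_mirna = 20L, pingpong_fraction = phi,
             library_depth = as.integer(depth), seed = as.integer(seed),
             ...)
}

# Independent brute-force exact mapper: per read, per feature, compare
# the read (and its reverse complement) against every offset.
brute_force_map <- function(reads, ref) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    rd <- reads$sequence[i]
    L <- nchar(rd)
    rdrc <- rc(rd)
    for (f in ref$features$id) {
      fseq <- as.character(ref$seqs[[f]])
      flen <- nchar(fseq)
      if (flen < L) next
      for (p in 0:(flen - L)) {
        w <- substr(fseq, p + 1L, p + L)
        if (w == rd)
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = reads$read_id[i], feature_id = f, strand = "+",
            five_prime = p, length = L, stringsAsFactors = FALSE)
        if (w == rdrc)
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = reads$read_id[i], feature_id = f, strand = "-",
            five_prime = p + L - 1L, length = L, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(read_id = character(0), feature_id = character(0),
                      strand = character(0), five_prime = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$read_id, out$feature_id, out$strand, out$five_prime), ,
      drop = FALSE]
}

# Independent all-pairs double-loop overlap histogram oracle.
brute_force_overlap <- function(alignments, ref, pirna_window = c(23, 30),
                                max_overlap = 25) {
  al <- alignments[alignments$length >= pirna_window[1] &
                   alignments$length <= pirna_window[2], , drop = FALSE]
  mass <- numeric(max_overlap)
  for (i in seq_len(nrow(al))) {
    for (j in seq_len(nrow(al))) {
      if (al$feature_id[i] != al$feature_id[j]) next
      if (al$strand[i] != "+" || al$strand[j] != "-") next
      o <- al$five_prime[j] - al$five_prime[i] + 1L
      if (o >= 1L && o <= max_overlap)
        mass[o] <- mass[o] + al$weight[i] * al$weight[j]
    }
  }
  mass
}

# Map + normalize one read set.
normalize_from_reads <- function(reads, ref, ...) {
  normalize_library(map_reads(reads, ref), ref, ...)
}

# Alignment-table sort key for set comparisons.
align_key <- function(al) {
  k <- paste(al$read_id, al$feature_id, al$strand, al$five_prime,
             al$length)
  sort(k)
}
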