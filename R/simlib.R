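#' Simulation configuration for synthetic piRNA/miRNA libraries
#'
#' Builds the configuration object consumed by [build_reference()],
#' [simulate_library()] and [simulate_knockdown_pair()]. The defaults
#' emulate an ovarian small-RNA library at desk scale: a panel of TE
#' consensus sequences, one uni-strand cluster assembled from antisense TE
#' fragments (flamenco-like) and one dual-strand cluster with random
#' fragment orientation (42AB-like), an invariant miRNA anchor population,
#' 1U-biased primary piRNAs with lengths in 23--30 nt, and ping-pong read
#' pairs whose 5' ends overlap by exactly 10 nt.
#'
#' @param n_te Number of TE consensus sequences.
#' @param te_length_range Integer interval (nt) for TE lengths.
#' @param cluster_spec List of cluster descriptions, each a list with
#'   elements `id`, `strand_mode` (`"uni"` or `"dual"`) and
#'   `fragment_count`. May be empty for a TE-only panel.
#' @param fragment_length_range Integer interval (nt) for cluster fragment
#'   lengths copied from TEs.
#' @param n_mirna Number of miRNA species.
#' @param mirna_length miRNA length in nt (default 22).
#' @param pirna_length_mean,pirna_length_sd Mean and sd (nt) of the
#'   truncated-normal piRNA length distribution.
#' @param pirna_length_bounds piRNA length window, must lie within
#'   \[18, 35\] nt.
#' @param u1_bias Probability beta in \[0,1\] that a primary (or ping-pong
#'   initiator) piRNA 5' nucleotide is uridine.
#' @param pingpong_fraction Per-TE probability phi in \[0,1\] that a TE
#'   piRNA read pair derives from the ping-pong cycle; a scalar recycles
#'   over TEs, or a vector of length `n_te`.
#' @param pingpong_sites Number of discrete ping-pong pair sites per TE.
#' @param mirna_fraction Expected fraction of library mass in miRNA reads.
#' @param cluster_share Fraction of piRNA mass assigned to clusters (0 if
#'   `cluster_spec` is empty).
#' @param primary_reduction Multiplicative factor r in \[0,1\] applied to
#'   primary-pathway expected counts in a knockdown library.
#' @param library_depth Target (expected) total read count.
#' @param seed Integer seed; identical (config, seed) pairs give
#'   byte-identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_te = 6L,
                       te_length_range = c(800L, 1500L),
                       cluster_spec = list(
                         list(id = "cluster_uni", strand_mode = "uni",
                              fragment_count = 8L),
                         list(id = "cluster_dual", strand_mode = "dual",
                              fragment_count = 8L)),
                       fragment_length_range = c(150L, 400L),
                       n_mirna = 40L,
                       mirna_length = 22L,
                       pirna_length_mean = 26,
                       pirna_length_sd = 1.5,
                       pirna_length_bounds = c(23L, 30L),
                       u1_bias = 0.9,
                       pingpong_fraction = 0.2,
                       pingpong_sites = 40L,
                       mirna_fraction = 0.25,
                       cluster_share = 0.4,
                       primary_reduction = 1,
                       library_depth = 50000L,
                       seed = 1L) {
  cfg <- structure(list(
    n_te = as.integer(n_te),
    te_length_range = as.integer(te_length_range),
    cluster_spec = cluster_spec,
    fragment_length_range = as.integer(fragment_length_range),
    n_mirna = as.integer(n_mirna),
    mirna_length = as.integer(mirna_length),
    pirna_length_mean = pirna_length_mean,
    pirna_length_sd = pirna_length_sd,
    pirna_length_bounds = as.integer(pirna_length_bounds),
    u1_bias = u1_bias,
    pingpong_fraction = pingpong_fraction,
    pingpong_sites = as.integer(pingpong_sites),
    mirna_fraction = mirna_fraction,
    cluster_share = if (length(cluster_spec)) cluster_share else 0,
    primary_reduction = primary_reduction,
    library_depth = as.integer(library_depth),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants of a [sim_config()] object: probability fields in
#' \[0,1\], counts >= 1, piRNA length bounds inside \[18, 35\] nt, and
#' non-degenerate length ranges.
#'
#' @param config A `sim_config` object.
#' @return The config, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  with(config, {
    if (n_te < 1L || n_mirna < 1L)
      stop("n_te and n_mirna must be >= 1")
    if (te_length_range[1] > te_length_range[2])
      stop("degenerate te_length_range: min > max")
    if (fragment_length_range[1] > fragment_length_range[2])
      stop("degenerate fragment_length_range: min > max")
    if (pirna_length_bounds[1] < 18L || pirna_length_bounds[2] > 35L ||
        pirna_length_bounds[1] > pirna_length_bounds[2])
      stop("pirna_length_bounds must be an interval within [18, 35]")
    for (p in list(u1_bias, mirna_fraction, cluster_share,
                   primary_reduction)) {
      if (any(p < 0 | p > 1)) stop("probability fields must lie in [0, 1]")
    }
    if (any(pingpong_fraction < 0 | pingpong_fraction > 1))
      stop("pingpong_fraction must lie in [0, 1]")
    if (is.null(names(pingpong_fraction)) &&
        !length(pingpong_fraction) %in% c(1L, n_te))
      stop("pingpong_fraction must be scalar, length n_te, or named by TE")
    if (library_depth < 0L) stop("library_depth must be >= 0")
    if (is.na(seed)) stop("seed is required")
  })
  invisible(config)
}

# Per-TE ping-pong fractions as a named vector over TE ids. A named input
# may cover a subset of TEs (others get 0); names must exist in the panel.
.phi_by_te <- function(config, te_ids) {
  phi <- config$pingpong_fraction
  if (!is.null(names(phi))) {
    unknown <- setdiff(names(phi), te_ids)
    if (length(unknown))
      stop("pingpong_fraction set for TE(s) absent from the reference: ",
           paste(unknown, collapse = ", "))
    out <- setNames(numeric(length(te_ids)), te_ids)
    out[names(phi)] <- phi
    return(out)
  }
  if (length(phi) == 1L) phi <- rep(phi, length(te_ids))
  setNames(phi, te_ids)
}

.rand_dna <- function(n_nt) {
  paste(sample(c("A", "C", "G", "T"), n_nt, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a synthetic reference panel
#'
#' Generates TE consensus sequences, piRNA cluster sequences assembled by
#' concatenating fragments copied from the TEs, and miRNA sequences.
#' Uni-strand clusters carry every fragment reverse-complemented relative
#' to its source TE (so cluster-derived primary piRNAs are antisense to the
#' TE, as for flamenco); dual-strand clusters use random fragment
#' orientation. Fragment provenance is recorded in 0-based half-open
#' cluster coordinates.
#'
#' @param config A [sim_config()] object (its `seed` fixes the reference).
#' @return A `reference_set`: list with `seqs` (named
#'   [Biostrings::DNAStringSet]), `features` (data.frame of id, class,
#'   length) and `fragments` (data.frame of cluster_id, start0, end0,
#'   source_te, te_start0, strand).
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  te_ids <- sprintf("te%02d", seq_len(config$n_te))
  te_len <- sample(seq(config$te_length_range[1], config$te_length_range[2]),
                   config$n_te, replace = TRUE)
  te_seq <- vapply(te_len, .rand_dna, character(1))
  names(te_seq) <- te_ids

  frag_rows <- list()
  cl_seq <- character(0)
  for (cl in config$cluster_spec) {
    stopifnot(cl$strand_mode %in% c("uni", "dual"))
    pieces <- character(cl$fragment_count)
    pos0 <- 0L
    for (k in seq_len(cl$fragment_count)) {
      src <- sample(te_ids, 1L)
      flen <- sample(seq(config$fragment_length_range[1],
                         config$fragment_length_range[2]), 1L)
      slen <- nchar(te_seq[[src]])
      if (flen > slen)
        stop(sprintf("fragment length %d exceeds source TE %s length %d",
                     flen, src, slen))
      te_start0 <- sample.int(slen - flen + 1L, 1L) - 1L
      frag <- substr(te_seq[[src]], te_start0 + 1L, te_start0 + flen)
      strand <- if (cl$strand_mode == "uni") "-" else
        sample(c("+", "-"), 1L)
      if (strand == "-") frag <- .revcomp(frag)
      pieces[k] <- frag
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        cluster_id = cl$id, start0 = pos0, end0 = pos0 + flen,
        source_te = src, te_start0 = te_start0, strand = strand,
        stringsAsFactors = FALSE)
      pos0 <- pos0 + flen
    }
    cl_seq[[cl$id]] <- paste(pieces, collapse = "")
  }

  mir_ids <- sprintf("mir%03d", seq_len(config$n_mirna))
  repeat {
    mir_seq <- vapply(rep(config$mirna_length, config$n_mirna),
                      .rand_dna, character(1))
    if (!anyDuplicated(mir_seq)) break
  }
  names(mir_seq) <- mir_ids

  seqs <- Biostrings::DNAStringSet(c(te_seq, cl_seq, mir_seq))
  features <- data.frame(
    id = names(seqs),
    class = c(rep("TE", config$n_te),
              rep("cluster", length(cl_seq)),
              rep("miRNA", config$n_mirna)),
    length = Biostrings::width(seqs),
    stringsAsFactors = FALSE)
  fragments <- if (length(frag_rows)) do.call(rbind, frag_rows) else NULL

  reference_set(seqs, features, fragments)
}

#' Construct a reference set
#'
#' Container for a panel of reference features (TE consensus, cluster,
#' miRNA, other) with their sequences and optional sub-feature intervals.
#'
#' @param seqs Named [Biostrings::DNAStringSet].
#' @param features data.frame with columns `id`, `class`
#'   (TE/cluster/miRNA/other) and `length`.
#' @param fragments Optional data.frame of sub-feature intervals in
#'   0-based half-open coordinates.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(seqs, features, fragments = NULL) {
  stopifnot(methods::is(seqs, "DNAStringSet"),
            all(c("id", "class", "length") %in% names(features)))
  if (anyDuplicated(features$id)) stop("duplicate feature id")
  if (!identical(unname(features$length),
                 unname(Biostrings::width(seqs)[match(features$id,
                                                      names(seqs))])))
    stop("feature lengths must equal sequence lengths")
  structure(list(seqs = seqs, features = features, fragments = fragments),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  tab <- table(x$features$class)
  cat("reference_set:",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), "\n")
  invisible(x)
}

# Feature ids of a given class.
.ids_of_class <- function(ref, cls) ref$features$id[ref$features$class %in% cls]

# -- internal samplers -------------------------------------------------------

# Discrete truncated-normal lengths.
.sample_lengths <- function(n, mean, sd, bounds) {
  if (n == 0L) return(integer(0))
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(rnorm(n - length(out) + 16L, mean, sd)))
    x <- x[x >= bounds[1] & x <= bounds[2]]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

# Sample n 5' start positions with an exact Bernoulli(beta) 1U mixture:
# with probability beta the position is drawn from `u_pos` (5' nucleotide
# is U/T), otherwise from `other_pos`. Falls back to the non-empty pool.
.sample_biased_pos <- function(n, u_pos, other_pos, beta) {
  if (n == 0L) return(integer(0))
  if (!length(u_pos)) return(other_pos[sample.int(length(other_pos), n,
                                                  replace = TRUE)])
  if (!length(other_pos)) return(u_pos[sample.int(length(u_pos), n,
                                                  replace = TRUE)])
  forced <- runif(n) < beta
  out <- integer(n)
  if (any(forced))
    out[forced] <- u_pos[sample.int(length(u_pos), sum(forced),
                                    replace = TRUE)]
  if (any(!forced))
    out[!forced] <- other_pos[sample.int(length(other_pos), sum(!forced),
                                         replace = TRUE)]
  out
}

# Structural (library-composition) draws shared between a control and its
# knockdown: species abundance weights and ping-pong pair sites. Seeded
# from config$seed + 1 so the reference (config$seed) is untouched.
.sim_structure <- function(ref, config) {
  set.seed(config$seed + 1L)
  te_ids <- .ids_of_class(ref, "TE")
  cl_ids <- .ids_of_class(ref, "cluster")
  mir_ids <- .ids_of_class(ref, "miRNA")
  phi <- .phi_by_te(config, te_ids)
  if (length(phi) != length(te_ids))
    stop("pingpong_fraction refers to TEs absent from the reference")

  w_mir <- rlnorm(length(mir_ids), 0, 1.25)
  w_mir <- setNames(w_mir / sum(w_mir), mir_ids)
  w_te <- rlnorm(length(te_ids), 0, 0.8)
  w_te <- setNames(w_te / sum(w_te), te_ids)
  w_cl <- if (length(cl_ids)) {
    w <- rlnorm(length(cl_ids), 0, 0.5)
    setNames(w / sum(w), cl_ids)
  } else numeric(0)

  lmax <- config$pirna_length_bounds[2]
  sites <- list()
  for (t in te_ids[phi > 0]) {
    s_char <- strsplit(as.character(ref$seqs[[t]]), "")[[1]]
    len <- length(s_char)
    lo <- lmax - 1L
    hi <- len - lmax + 9L
    if (hi < lo) stop(sprintf("TE %s too short for ping-pong pairs", t))
    cand <- lo:hi
    # initiator is antisense with 5' at a; its first nt is complement of
    # the TE base at a, so a U-start initiator needs TE[a] == A
    a_pos <- cand[s_char[cand + 1L] == "A"]
    n_pos <- setdiff(cand, a_pos)
    a <- .sample_biased_pos(config$pingpong_sites, a_pos, n_pos,
                            config$u1_bias)
    w <- rlnorm(length(a), 0, 0.4)
    sites[[t]] <- data.frame(a = a, w = w / sum(w))
  }

  list(te_ids = te_ids, cl_ids = cl_ids, mir_ids = mir_ids, phi = phi,
       w_mir = w_mir, w_te = w_te, w_cl = w_cl, sites = sites)
}

# Emit primary piRNA read instances from one transcript.
#  sense = TRUE  : reads are sense substrings of the feature (clusters)
#  sense = FALSE : reads are reverse-complement substrings (antisense TE)
# Returns character vector of read sequences plus the 5' coordinates used.
.emit_primary <- function(seq_char, n, config, sense) {
  if (n == 0L)
    return(list(seq = character(0), five_prime = integer(0),
                len = integer(0)))
  chars <- strsplit(seq_char, "")[[1]]
  len <- length(chars)
  lens <- .sample_lengths(n, config$pirna_length_mean,
                          config$pirna_length_sd,
                          config$pirna_length_bounds)
  fp <- integer(n)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (sense) {
      elig <- 0:(len - L)
      upos <- elig[chars[elig + 1L] == "T"]
    } else {
      elig <- (L - 1L):(len - 1L)
      upos <- elig[chars[elig + 1L] == "A"]  # antisense 5' is complement
    }
    fp[idx] <- .sample_biased_pos(length(idx), upos, setdiff(elig, upos),
                                  config$u1_bias)
  }
  seqs <- if (sense) substring(seq_char, fp + 1L, fp + lens) else
    .revcomp(substring(seq_char, fp - lens + 2L, fp + 1L))
  list(seq = seqs, five_prime = fp, len = lens)
}

# Sample read instances for one library given the shared structure.
# `r` scales the primary-pathway expected counts (clusters + antisense-TE
# primary arm); the ping-pong arm and miRNA anchors are unscaled.
.sample_reads <- function(ref, config, str, r) {
  depth <- config$library_depth
  e_mir <- depth * config$mirna_fraction
  e_pi <- depth * (1 - config$mirna_fraction)
  cl_share <- if (length(str$cl_ids)) config$cluster_share else 0
  e_cl <- e_pi * cl_share * str$w_cl
  e_te <- e_pi * (1 - cl_share) * str$w_te

  seqs <- character(0)
  mir_counts <- rpois(length(str$mir_ids), e_mir * str$w_mir)
  names(mir_counts) <- str$mir_ids
  if (sum(mir_counts) > 0)
    seqs <- c(seqs, rep(as.character(ref$seqs[str$mir_ids]), mir_counts))

  cl_primary <- setNames(numeric(length(str$cl_ids)), str$cl_ids)
  for (cl in str$cl_ids) {
    n <- rpois(1L, r * e_cl[[cl]])
    em <- .emit_primary(as.character(ref$seqs[[cl]]), n, config,
                        sense = TRUE)
    cl_primary[[cl]] <- n
    seqs <- c(seqs, em$seq)
  }

  te_primary <- setNames(numeric(length(str$te_ids)), str$te_ids)
  te_pp <- setNames(numeric(length(str$te_ids)), str$te_ids)
  init_u1 <- 0; resp_a10 <- 0; pp_pairs <- 0
  for (t in str$te_ids) {
    s_char <- as.character(ref$seqs[[t]])
    phi_t <- str$phi[[t]]
    n_prim <- rpois(1L, r * e_te[[t]] * (1 - phi_t))
    em <- .emit_primary(s_char, n_prim, config, sense = FALSE)
    te_primary[[t]] <- n_prim
    seqs <- c(seqs, em$seq)

    if (phi_t > 0) {
      st <- str$sites[[t]]
      npair <- rpois(nrow(st), e_te[[t]] * phi_t * st$w / 2)
      tot <- sum(npair)
      if (tot > 0) {
        a <- rep(st$a, npair)
        li <- .sample_lengths(tot, config$pirna_length_mean,
                              config$pirna_length_sd,
                              config$pirna_length_bounds)
        lr <- .sample_lengths(tot, config$pirna_length_mean,
                              config$pirna_length_sd,
                              config$pirna_length_bounds)
        initiator <- .revcomp(substring(s_char, a - li + 2L, a + 1L))
        responder <- substring(s_char, a - 9L + 1L, a - 9L + lr)
        seqs <- c(seqs, initiator, responder)
        base_a <- substring(s_char, a + 1L, a + 1L) == "A"
        init_u1 <- init_u1 + sum(base_a)    # initiator 5' U <=> TE[a] == A
        resp_a10 <- resp_a10 + sum(base_a)  # responder pos 10 == TE[a]
        pp_pairs <- pp_pairs + tot
      }
      te_pp[[t]] <- 2 * tot
    }
  }

  truth <- list(
    per_mirna = mir_counts,
    per_cluster_primary = cl_primary,
    per_te_primary = te_primary,
    per_te_pingpong = te_pp,
    class_masses = c(miRNA = sum(mir_counts),
                     primary = sum(cl_primary) + sum(te_primary),
                     pingpong = sum(te_pp)),
    pingpong_pairs = pp_pairs,
    initiator_u1_fraction = if (pp_pairs > 0) init_u1 / pp_pairs else NA_real_,
    responder_a10_fraction = if (pp_pairs > 0) resp_a10 / pp_pairs else NA_real_,
    realized_r = r,
    seed = config$seed,
    fragments = ref$fragments)
  truth$total_reads <- sum(truth$class_masses)

  list(seqs = seqs, truth = truth)
}

# Collapse a vector of read instance sequences into a read_set data.frame.
.collapse_reads <- function(seqs) {
  if (!length(seqs))
    return(data.frame(read_id = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  tab <- table(seqs)
  sq <- sort(names(tab))
  data.frame(read_id = sprintf("r%06d", seq_along(sq)),
             sequence = sq,
             count = as.integer(tab[sq]),
             stringsAsFactors = FALSE)
}

#' Simulate one small-RNA library with ground truth
#'
#' Emits reads of three classes: (a) miRNA reads, exact copies of the miRNA
#' references with heavy-tailed (log-normal rate, Poisson count)
#' abundances; (b) primary piRNAs, exact substrings of cluster transcripts
#' (sense) and antisense-TE transcripts, with 5' positions uniform over the
#' eligible transcript, a Bernoulli(beta) 1U mixture at the 5' nucleotide,
#' and truncated-normal lengths; (c) ping-pong pairs for TEs with phi > 0:
#' an antisense initiator and a sense responder whose 5' ends overlap by
#' exactly 10 nt, so the responder's position 10 is complementary to the
#' initiator's position 1 (a 1U initiator forces a 10A responder).
#'
#' @param ref A `reference_set` built by [build_reference()] from a
#'   compatible configuration.
#' @param config A [sim_config()]; its `seed` drives both composition and
#'   sampling draws (offsets +1 and +2 of the reference seed).
#' @return A list with `reads` (collapsed read_set data.frame: read_id,
#'   sequence, count) and `truth` (per-class/per-feature read masses, the
#'   realized primary reduction, 1U/10A accounting, and fragment
#'   provenance).
#' @export
simulate_library <- function(ref, config) {
  validate_sim_config(config)
  stopifnot(inherits(ref, "reference_set"))
  str <- .sim_structure(ref, config)
  set.seed(config$seed + 2L)
  out <- .sample_reads(ref, config, str, r = 1)
  list(reads = .collapse_reads(out$seqs), truth = out$truth)
}

#' Simulate a matched control/knockdown library pair
#'
#' Control and knockdown share one generative draw of the library
#' composition (species abundances, ping-pong pair sites); the knockdown
#' multiplies all primary-pathway expected counts by `config$primary_reduction`
#' before Poisson sampling, while miRNA expectations are identical in both
#' libraries and ping-pong pair expectations are unscaled.
#'
#' @inheritParams simulate_library
#' @return A list with `control` and `knockdown` (read_set data.frames)
#'   and `truth` (list with per-library truths and the applied `r`).
#' @export
simulate_knockdown_pair <- function(ref, config) {
  validate_sim_config(config)
  stopifnot(inherits(ref, "reference_set"))
  r <- config$primary_reduction
  if (r < 0 || r > 1) stop("primary_reduction must lie in [0, 1]")
  str <- .sim_structure(ref, config)
  set.seed(config$seed + 2L)
  ctrl <- .sample_reads(ref, config, str, r = 1)
  set.seed(config$seed + 3L)
  kd <- .sample_reads(ref, config, str, r = r)
  list(control = .collapse_reads(ctrl$seqs),
       knockdown = .collapse_reads(kd$seqs),
       truth = list(control = ctrl$truth, knockdown = kd$truth, r = r))
}
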