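#' Map collapsed reads onto a reference panel (exact, strand-aware)
#'
#' Reports every exact occurrence of each read on both strands of every
#' feature. Matching is exact (0 mismatches). The 5' coordinate convention
#' is strand-aware: for a plus-strand hit `five_prime` is the feature
#' coordinate (0-based) of the leftmost matched base; for a minus-strand
#' hit it is the feature coordinate of the read's biological 5'
#' nucleotide, i.e. the rightmost matched base. This convention makes the
#' ping-pong overlap arithmetic (antisense 5' minus sense 5' plus 1) exact.
#'
#' Each read's count is split evenly over its retained hits
#' (`weight = count / n_hits`); reads with more than `max_hits` hits are
#' discarded, reads with none are recorded as unmapped.
#'
#' @param reads A read_set data.frame (`read_id`, `sequence`, `count`).
#' @param ref A `reference_set`.
#' @param max_hits Discard reads with more hits than this (default 100).
#' @return An alignment table: data.frame with columns `read_id`,
#'   `feature_id`, `strand` (+/-), `five_prime` (0-based), `length`,
#'   `weight`, `unique`. Attributes: `reads` (the input read_set),
#'   `unmapped` and `discarded` (read ids).
#' @export
map_reads <- function(reads, ref, max_hits = 100L) {
  stopifnot(inherits(ref, "reference_set"),
            all(c("read_id", "sequence", "count") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$sequence) < 18L))
    stop("reads shorter than 18 nt are not supported")

  feat_ids <- ref$features$id
  feat_len <- ref$features$length
  # One subject per reference: features joined by N spacers longer than
  # any read, so exact ACGT matches cannot cross feature boundaries.
  spacer <- 40L
  offset0 <- cumsum(c(0L, head(feat_len + spacer, -1L)))  # 0-based starts
  subject <- paste(as.character(ref$seqs[feat_ids]),
                   collapse = strrep("N", spacer))
  nsub <- nchar(subject)

  # Exact matching by hash join: every length-L window of the subject is
  # looked up in the (unique, collapsed) read sequences of that length,
  # on both strands. Windows crossing the N spacers can never equal an
  # ACGT read, so features stay isolated.
  hits <- list()
  lens <- nchar(reads$sequence)
  for (L in sort(unique(lens))) {
    if (L > nsub) next
    idx <- which(lens == L)
    fwd <- reads$sequence[idx]
    rev <- .revcomp(fwd)
    starts <- seq_len(nsub - L + 1L)
    subs <- substring(subject, starts, starts + L - 1L)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fwd else rev
      hit <- which(subs %in% pat)
      if (!length(hit)) next
      st0 <- hit - 1L                      # 0-based global start
      fi <- findInterval(st0, offset0)
      local0 <- st0 - offset0[fi]
      hits[[length(hits) + 1L]] <- data.frame(
        ri = idx[match(subs[hit], pat)], feature_id = feat_ids[fi],
        strand = strand,
        five_prime = if (strand == "+") local0 else local0 + L - 1L,
        length = L, stringsAsFactors = FALSE)
    }
  }

  if (!length(hits)) {
    al <- data.frame(read_id = character(0), feature_id = character(0),
                     strand = character(0), five_prime = integer(0),
                     length = integer(0), weight = numeric(0),
                     unique = logical(0), stringsAsFactors = FALSE)
    attr(al, "reads") <- reads
    attr(al, "unmapped") <- reads$read_id
    attr(al, "discarded") <- character(0)
    return(al)
  }

  h <- do.call(rbind, hits)
  nhits <- tabulate(h$ri, nbins = nrow(reads))
  keep_read <- nhits >= 1L & nhits <= max_hits
  discarded <- reads$read_id[nhits > max_hits]
  unmapped <- reads$read_id[nhits == 0L]
  if (length(discarded))
    message(length(discarded), " read(s) with > ", max_hits,
            " hits discarded")
  h <- h[keep_read[h$ri], , drop = FALSE]
  al <- data.frame(read_id = reads$read_id[h$ri],
                   feature_id = h$feature_id,
                   strand = h$strand,
                   five_prime = h$five_prime,
                   length = h$length,
                   weight = reads$count[h$ri] / nhits[h$ri],
                   unique = nhits[h$ri] == 1L,
                   stringsAsFactors = FALSE)
  al <- al[order(al$read_id, al$feature_id, al$strand, al$five_prime), ,
           drop = FALSE]
  rownames(al) <- NULL
  attr(al, "reads") <- reads
  attr(al, "unmapped") <- unmapped
  attr(al, "discarded") <- discarded
  al
}

#' Per-class weighted read counts
#'
#' Sums alignment weights by feature class (miRNA/TE/cluster/other) and,
#' within each class, by read length. A read hitting features of several
#' classes contributes to each class in proportion to its per-hit weights.
#'
#' @param alignments An alignment table from [map_reads()].
#' @param ref The `reference_set` the alignments refer to.
#' @return A list with `by_class` (named numeric of weighted counts) and
#'   `by_class_length` (data.frame class, length, weight).
#' @export
class_counts <- function(alignments, ref) {
  stopifnot(inherits(ref, "reference_set"))
  cls <- ref$features$class[match(alignments$feature_id, ref$features$id)]
  if (anyNA(cls)) stop("alignment references unknown feature")
  all_classes <- c("miRNA", "TE", "cluster", "other")
  by_class <- setNames(numeric(length(all_classes)), all_classes)
  if (nrow(alignments)) {
    s <- tapply(alignments$weight, cls, sum)
    by_class[names(s)] <- s
  }
  bcl <- if (nrow(alignments)) {
    agg <- aggregate(weight ~ cls + length,
                     data = data.frame(cls = cls,
                                       length = alignments$length,
                                       weight = alignments$weight),
                     FUN = sum)
    names(agg)[1] <- "class"
    agg[order(agg$class, agg$length), , drop = FALSE]
  } else {
    data.frame(class = character(0), length = integer(0),
               weight = numeric(0))
  }
  rownames(bcl) <- NULL
  list(by_class = by_class, by_class_length = bcl)
}

#' Write an alignment table as TSV
#'
#' @param alignments Alignment table from [map_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
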