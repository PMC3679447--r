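#' miRNA-anchored library normalization
#'
#' Normalizes a small-RNA library to its miRNA content: all downstream
#' quantities are reported in reads per million miRNA-mapped reads (RPMM).
#' miRNAs are used as the anchor because their abundance is invariant to
#' piRNA-pathway perturbations, so knockdown and control libraries become
#' directly comparable.
#'
#' @param alignments Alignment table from [map_reads()].
#' @param ref The `reference_set` used for mapping.
#' @param pirna_window piRNA length window in nt (default 23--30), used by
#'   downstream profile/signature functions.
#' @return A `normalized_library`: list with `alignments`, `ref`,
#'   `mirna_total` (weighted miRNA-mapped count), `factor`
#'   (`1e6 / mirna_total`) and `pirna_window`.
#' @export
normalize_library <- function(alignments, ref, pirna_window = c(23L, 30L)) {
  stopifnot(inherits(ref, "reference_set"))
  cls <- ref$features$class[match(alignments$feature_id, ref$features$id)]
  mirna_total <- sum(alignments$weight[cls == "miRNA"])
  if (!isTRUE(mirna_total > 0))
    stop("no miRNA-mapped reads: the miRNA normalization anchor is ",
         "missing; check that the reference panel contains miRNA-class ",
         "features and that reads map to them")
  structure(list(alignments = alignments, ref = ref,
                 mirna_total = mirna_total,
                 factor = 1e6 / mirna_total,
                 pirna_window = as.integer(pirna_window)),
            class = "normalized_library")
}

#' @export
print.normalized_library <- function(x, ...) {
  cat(sprintf(paste0("normalized_library: %d alignments, miRNA total ",
                     "%.1f, factor %.4g, piRNA window [%d, %d]\n"),
              nrow(x$alignments), x$mirna_total, x$factor,
              x$pirna_window[1], x$pirna_window[2]))
  invisible(x)
}

# Alignment rows inside the piRNA length window.
.pirna_rows <- function(lib) {
  al <- lib$alignments
  al[al$length >= lib$pirna_window[1] &
     al$length <= lib$pirna_window[2], , drop = FALSE]
}

# Feature class for each alignment row.
.row_class <- function(al, ref) {
  ref$features$class[match(al$feature_id, ref$features$id)]
}

#' Signed 5'-end coverage profile of one feature
#'
#' Per-position RPMM mass of piRNA-window read 5' ends on a feature:
#' sense alignments contribute positive values, antisense negative
#' (the "sense up, antisense down" display convention). Only 5' ends are
#' recorded, as these are the quantity entering the overlap analysis.
#'
#' @param lib A `normalized_library`.
#' @param feature_id Feature to profile.
#' @param unique_only If TRUE, restrict to uniquely mapping reads.
#' @return Numeric matrix with `feature length` rows and columns `sense`
#'   (non-negative) and `antisense` (non-positive); row `i` is the RPMM
#'   5'-end mass at 0-based position `i - 1`. Keeping the strands as
#'   separate signed components means `sum(abs(profile))` equals the
#'   total mapped piRNA-window mass even where both strands share a
#'   position.
#' @export
coverage_profile <- function(lib, feature_id, unique_only = FALSE) {
  stopifnot(inherits(lib, "normalized_library"))
  fi <- match(feature_id, lib$ref$features$id)
  if (is.na(fi)) stop("unknown feature: ", feature_id)
  len <- lib$ref$features$length[fi]
  al <- .pirna_rows(lib)
  al <- al[al$feature_id == feature_id, , drop = FALSE]
  if (unique_only) al <- al[al$unique, , drop = FALSE]
  prof <- matrix(0, nrow = len, ncol = 2,
                 dimnames = list(NULL, c("sense", "antisense")))
  for (strand in c("+", "-")) {
    as_ <- al[al$strand == strand, , drop = FALSE]
    if (!nrow(as_)) next
    v <- tapply(as_$weight * lib$factor, as_$five_prime, sum)
    col <- if (strand == "+") "sense" else "antisense"
    prof[as.integer(names(v)) + 1L, col] <-
      if (strand == "+") v else -v
  }
  prof
}

#' Length histogram of normalized small-RNA populations
#'
#' Weighted, RPMM-normalized 5'-end mass per read length (18--35 nt),
#' split by orientation (sense/antisense) and feature class.
#'
#' @param lib A `normalized_library`.
#' @param classes Feature classes to include (default all).
#' @param orientation `"both"`, `"sense"` or `"antisense"`.
#' @return data.frame with columns `class`, `length`, `orientation`,
#'   `rpmm`, covering the full 18--35 nt grid (zero-filled).
#' @export
length_histogram <- function(lib, classes = c("miRNA", "TE", "cluster",
                                              "other"),
                             orientation = c("both", "sense",
                                             "antisense")) {
  stopifnot(inherits(lib, "normalized_library"))
  orientation <- match.arg(orientation)
  al <- lib$alignments
  cls <- .row_class(al, lib$ref)
  keep <- cls %in% classes
  if (orientation == "sense") keep <- keep & al$strand == "+"
  if (orientation == "antisense") keep <- keep & al$strand == "-"
  al <- al[keep, , drop = FALSE]
  cls <- cls[keep]
  ori <- ifelse(al$strand == "+", "sense", "antisense")
  grid <- expand.grid(class = classes, length = 18:35,
                      orientation = if (orientation == "both")
                        c("sense", "antisense") else orientation,
                      stringsAsFactors = FALSE)
  grid$rpmm <- 0
  if (nrow(al)) {
    agg <- aggregate(w ~ class + length + orientation,
                     data = data.frame(class = cls, length = al$length,
                                       orientation = ori,
                                       w = al$weight * lib$factor),
                     FUN = sum)
    k <- match(paste(agg$class, agg$length, agg$orientation),
               paste(grid$class, grid$length, grid$orientation))
    grid$rpmm[k[!is.na(k)]] <- agg$w[!is.na(k)]
  }
  grid[order(grid$class, grid$length, grid$orientation), , drop = FALSE]
}

#' RPKM expression table
#'
#' Reads per kilobase of feature per million mapped reads:
#' `rpkm = count / (length/1000) / (total_mapped/1e6)`.
#'
#' @param counts Numeric vector of raw per-gene counts.
#' @param lengths Numeric vector of gene lengths in nt (> 0).
#' @param total_mapped Total mapped reads of the library (> 0).
#' @param gene_ids Gene identifiers (defaults to `names(counts)` or an
#'   index).
#' @return data.frame with columns `gene_id`, `count`, `length`, `rpkm`.
#' @export
rpkm_table <- function(counts, lengths, total_mapped, gene_ids = NULL) {
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (total_mapped <= 0) stop("total_mapped must be > 0")
  if (length(counts) != length(lengths))
    stop("counts and lengths must have equal length")
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(names(counts))) names(counts) else
      sprintf("gene%05d", seq_along(counts))
  data.frame(gene_id = gene_ids, count = counts, length = lengths,
             rpkm = counts / (lengths / 1e3) / (total_mapped / 1e6),
             stringsAsFactors = FALSE)
}

#' Filter genes by RPKM cutoff
#'
#' Returns genes with `rpkm >= cutoff`. The comparison is inclusive.
#'
#' @param table An RPKM table from [rpkm_table()].
#' @param cutoff RPKM threshold (default 1).
#' @return Character vector of gene ids passing the cutoff.
#' @export
filter_expressed <- function(table, cutoff = 1) {
  table$gene_id[table$rpkm >= cutoff]
}
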