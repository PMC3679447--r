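#' Ping-pong 5'-overlap histogram
#'
#' For every feature and every (sense, antisense) pair of piRNA-window
#' alignments on it, the 5'-5' overlap is
#' `o = antisense_five_prime - sense_five_prime + 1`; pairs with
#' `1 <= o <= max_overlap` add the product of the two alignment weights to
#' bin `o`. Ping-pong amplification produces pairs with `o = 10`, so a
#' peak at bin 10 is the ping-pong signature. Pairs across different
#' features are ignored; bin masses are converted to fractions and scored
#' with [pingpong_z()].
#'
#' @param lib A `normalized_library`.
#' @param features Feature ids to analyse (default: all TE-class
#'   features).
#' @param max_overlap Largest overlap bin (default 25).
#' @param z_threshold Significance threshold on the bin-10 z-score
#'   (default 3).
#' @return An `overlap_histogram`: list with `mass` (weighted pair mass
#'   per bin), `fraction`, `z10`, `significant`, `total_mass`.
#' @export
overlap_histogram <- function(lib, features = NULL, max_overlap = 25L,
                              z_threshold = 3) {
  stopifnot(inherits(lib, "normalized_library"))
  if (is.null(features)) features <- .ids_of_class(lib$ref, "TE")
  al <- .pirna_rows(lib)
  al <- al[al$feature_id %in% features, , drop = FALSE]
  mass <- numeric(max_overlap)
  for (f in unique(al$feature_id)) {
    af <- al[al$feature_id == f, , drop = FALSE]
    len <- lib$ref$features$length[match(f, lib$ref$features$id)]
    s <- numeric(len); a <- numeric(len)
    sp <- af[af$strand == "+", , drop = FALSE]
    ap <- af[af$strand == "-", , drop = FALSE]
    if (!nrow(sp) || !nrow(ap)) next
    vs <- tapply(sp$weight, sp$five_prime, sum)
    s[as.integer(names(vs)) + 1L] <- vs
    va <- tapply(ap$weight, ap$five_prime, sum)
    a[as.integer(names(va)) + 1L] <- va
    for (o in seq_len(max_overlap)) {
      if (o > len) break
      mass[o] <- mass[o] + sum(s[1:(len - o + 1L)] * a[o:len])
    }
  }
  total <- sum(mass)
  frac <- if (total > 0) mass / total else mass
  hist <- structure(list(mass = mass, fraction = frac,
                         total_mass = total),
                    class = "overlap_histogram")
  z <- pingpong_z(hist, z_threshold = z_threshold)
  hist$z10 <- z$z10
  hist$significant <- z$significant
  hist
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat(sprintf("overlap_histogram: total pair mass %.3g, z10 = %.2f%s\n",
              x$total_mass, x$z10,
              if (isTRUE(x$significant)) " (significant)" else ""))
  invisible(x)
}

#' Bin-10 z-score of an overlap histogram
#'
#' `z10 = (f10 - mean(f_o, o != 10)) / sd(f_o, o != 10)` with the sample
#' (n-1) standard deviation over all non-10 bins. The histogram is called
#' significant when `z10 >= z_threshold`. Degenerate cases: zero total
#' mass or `sd = 0` with `f10` equal to the background mean give `z10 = 0`
#' (not significant); `sd = 0` with `f10` above the mean gives the `+Inf`
#' sentinel (significant).
#'
#' @param hist An `overlap_histogram` (or a bare numeric vector of bin
#'   masses).
#' @param z_threshold Significance threshold (default 3).
#' @return List with `z10` and `significant`.
#' @export
pingpong_z <- function(hist, z_threshold = 3) {
  mass <- if (inherits(hist, "overlap_histogram")) hist$mass else
    as.numeric(hist)
  if (length(mass) < 11L)
    stop("histogram must extend at least to overlap 11")
  total <- sum(mass)
  if (total == 0) return(list(z10 = 0, significant = FALSE))
  f <- mass / total
  bg <- f[-10L]
  m <- mean(bg)
  s <- sd(bg)
  if (s == 0) {
    if (f[10L] > m) return(list(z10 = Inf, significant = TRUE))
    return(list(z10 = 0, significant = FALSE))
  }
  z <- (f[10L] - m) / s
  list(z10 = z, significant = z >= z_threshold)
}

#' Positional nucleotide bias (e.g. 10A) of mapped reads
#'
#' Computes the weighted fraction of selected reads carrying `nucleotide`
#' at `position` (1-based within the read, in the read's own 5'-3'
#' orientation), and the expected fraction as the mean over
#' `background_positions` of the weighted per-position fractions. The
#' canonical use is adenosine at position 10 of sense TE piRNAs (the
#' ping-pong responder signature), with background positions 2--9 and
#' 11--23.
#'
#' Reads shorter than a queried position are excluded from that position's
#' tally only.
#'
#' @param lib A `normalized_library` (alignments must carry the read set,
#'   as produced by [map_reads()]).
#' @param orientation `"sense"` or `"antisense"` alignments to use.
#' @param position Queried read position (1-based).
#' @param nucleotide Queried base (one of A/C/G/T; U is treated as T).
#' @param background_positions Positions defining the expected level.
#' @param classes Feature classes whose alignments are used (default TE).
#' @return A `bias_result`: list with `position`, `nucleotide`,
#'   `observed`, `expected`, `excess` (observed - expected), `n_weighted`;
#'   all statistics are `NA` (flagged via `defined = FALSE`) when no read
#'   qualifies.
#' @export
positional_bias <- function(lib, orientation = c("sense", "antisense"),
                            position = 10L, nucleotide = "A",
                            background_positions = c(2:9, 11:23),
                            classes = "TE") {
  stopifnot(inherits(lib, "normalized_library"))
  orientation <- match.arg(orientation)
  nucleotide <- chartr("U", "T", toupper(nucleotide))
  stopifnot(nucleotide %in% c("A", "C", "G", "T"))
  reads <- attr(lib$alignments, "reads")
  if (is.null(reads))
    stop("alignment table lacks the read-set attribute; use map_reads()")
  al <- .pirna_rows(lib)
  cls <- .row_class(al, lib$ref)
  al <- al[cls %in% classes &
           al$strand == (if (orientation == "sense") "+" else "-"), ,
           drop = FALSE]
  if (!nrow(al))
    return(structure(list(position = position, nucleotide = nucleotide,
                          observed = NA_real_, expected = NA_real_,
                          excess = NA_real_, n_weighted = 0,
                          defined = FALSE), class = "bias_result"))
  seqs <- reads$sequence[match(al$read_id, reads$read_id)]
  w <- al$weight

  frac_at <- function(pos) {
    ok <- nchar(seqs) >= pos
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * (substring(seqs[ok], pos, pos) == nucleotide)) / sum(w[ok])
  }
  observed <- frac_at(position)
  bg <- vapply(background_positions, frac_at, numeric(1))
  expected <- mean(bg, na.rm = TRUE)
  ok_obs <- nchar(seqs) >= position
  structure(list(position = position, nucleotide = nucleotide,
                 observed = observed, expected = expected,
                 excess = observed - expected,
                 n_weighted = sum(w[ok_obs]),
                 defined = !is.na(observed)),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(paste0("bias_result: %s at position %d: observed %.3f, ",
                     "expected %.3f (excess %+.3f, n = %.1f)\n"),
              x$nucleotide, x$position, x$observed, x$expected, x$excess,
              x$n_weighted))
  invisible(x)
}
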