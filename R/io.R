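#' Read and collapse a small-RNA library
#'
#' Reads adapter-trimmed small-RNA sequences from FASTA or FASTQ, maps
#' U to T, drops reads outside the length window (logged as a message),
#' and collapses identical sequences with summed counts.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"fastq"`.
#' @param length_window Integer interval of retained read lengths (nt).
#' @return A read_set data.frame with columns `read_id`, `sequence`,
#'   `count`. Attribute `dropped` records the number of reads removed by
#'   the length filter.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           length_window = c(18L, 35L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty input file: ", path)
    out <- .collapse_reads(character(0))
    attr(out, "dropped") <- 0L
    return(out)
  }
  x <- Biostrings::readBStringSet(path, format = format)
  seqs <- chartr("acgtu", "ACGTT", chartr("U", "T", as.character(x)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warning(sum(bad), " read(s) with non-ACGTU characters dropped")
    seqs <- seqs[!bad]
  }
  keep <- nchar(seqs) >= length_window[1] & nchar(seqs) <= length_window[2]
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " read(s) outside length window [",
            length_window[1], ", ", length_window[2], "] dropped")
  out <- .collapse_reads(seqs[keep])
  attr(out, "dropped") <- dropped
  out
}

#' Write a read set to FASTA or FASTQ
#'
#' Each collapsed record is expanded into `count` identical read instances
#' (ids `<read_id>_1`, `<read_id>_2`, ...), so a write/read round trip
#' conserves total read counts. FASTQ qualities are fixed at "I".
#'
#' @param reads A read_set data.frame (`read_id`, `sequence`, `count`).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  n <- rep(seq_len(nrow(reads)), reads$count)
  inst <- Biostrings::DNAStringSet(reads$sequence[n])
  names(inst) <- paste0(reads$read_id[n],
                        "_", sequence(reads$count))
  if (format == "fasta") {
    Biostrings::writeXStringSet(inst, path, format = "fasta")
  } else {
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence[n])))
    Biostrings::writeXStringSet(inst, path, format = "fastq",
                                qualities = quals)
  }
  invisible(path)
}

#' Load a reference panel from FASTA (+ optional BED and class map)
#'
#' Features are classed through an explicit id-to-class map; ids missing
#' from the map are classed `"other"` with a warning. BED intervals
#' (0-based half-open, strand in column 6) become sub-feature fragments
#' and must name FASTA contigs and lie within them.
#'
#' @param fasta_path Reference FASTA.
#' @param bed_path Optional 6-column BED of sub-feature intervals.
#' @param class_map Named character vector (id -> class), a 2-column
#'   data.frame, or a path to a 2-column TSV (id, class).
#' @return A `reference_set`.
#' @export
load_annotations <- function(fasta_path, bed_path = NULL, class_map = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate feature id in ", fasta_path)

  cm <- .as_class_map(class_map)
  cls <- unname(cm[names(seqs)])
  if (any(is.na(cls))) {
    warning(sum(is.na(cls)), " feature(s) without class assignment ",
            "classed as 'other'")
    cls[is.na(cls)] <- "other"
  }
  features <- data.frame(id = names(seqs), class = cls,
                         length = Biostrings::width(seqs),
                         stringsAsFactors = FALSE)

  fragments <- NULL
  if (!is.null(bed_path)) {
    gr <- rtracklayer::import(bed_path, format = "BED")
    contig <- as.character(GenomicRanges::seqnames(gr))
    missing <- setdiff(contig, names(seqs))
    if (length(missing))
      stop("BED interval(s) on unknown contig(s): ",
           paste(unique(missing), collapse = ", "))
    len <- features$length[match(contig, features$id)]
    if (any(GenomicRanges::end(gr) > len))
      stop("BED interval exceeds contig length")
    fragments <- data.frame(
      cluster_id = contig,
      start0 = GenomicRanges::start(gr) - 1L,
      end0 = GenomicRanges::end(gr),
      source_te = if (!is.null(gr$name)) as.character(gr$name)
                  else NA_character_,
      te_start0 = NA_integer_,
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  }
  reference_set(seqs, features, fragments)
}

.as_class_map <- function(class_map) {
  if (is.null(class_map)) return(character(0))
  if (is.character(class_map) && length(class_map) == 1L &&
      is.null(names(class_map)) && file.exists(class_map)) {
    df <- read.table(class_map, sep = "\t", header = FALSE,
                     col.names = c("id", "class"),
                     stringsAsFactors = FALSE)
    return(setNames(df$class, df$id))
  }
  if (is.data.frame(class_map))
    return(setNames(as.character(class_map[[2]]),
                    as.character(class_map[[1]])))
  if (is.character(class_map) && !is.null(names(class_map)))
    return(class_map)
  stop("class_map must be a named vector, 2-column data.frame, or TSV path")
}

#' Write a reference panel to FASTA, BED and class-map TSV
#'
#' Inverse of [load_annotations()]: sequences to FASTA, sub-feature
#' fragments (if any) to 6-column BED (0-based half-open, source feature
#' in the name column, strand in column 6), feature classes to a
#' 2-column TSV.
#'
#' @param ref A `reference_set`.
#' @param fasta_path Output FASTA path.
#' @param bed_path Optional output BED path (written only if the reference
#'   carries fragments).
#' @param class_map_path Optional output TSV path for the id -> class map.
#' @return `fasta_path`, invisibly.
#' @export
write_reference <- function(ref, fasta_path, bed_path = NULL,
                            class_map_path = NULL) {
  stopifnot(inherits(ref, "reference_set"))
  Biostrings::writeXStringSet(ref$seqs, fasta_path)
  if (!is.null(bed_path) && !is.null(ref$fragments)) {
    fr <- ref$fragments
    gr <- GenomicRanges::GRanges(
      seqnames = fr$cluster_id,
      ranges = IRanges::IRanges(start = fr$start0 + 1L, end = fr$end0),
      strand = fr$strand,
      name = fr$source_te,
      score = 0L)
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  if (!is.null(class_map_path)) {
    write.table(ref$features[, c("id", "class")], class_map_path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Write simulation ground truth as JSON
#'
#' Serializes a `truth` list from [simulate_library()] or
#' [simulate_knockdown_pair()] as a JSON side-car.
#'
#' @param truth Truth list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
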