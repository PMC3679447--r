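#' Per-TE normalized piRNA levels
#'
#' Weighted piRNA-window 5'-end mass per TE feature in the requested
#' orientation, in RPMM units. TEs without mapped piRNAs report 0.
#'
#' @param lib A `normalized_library`.
#' @param orientation `"antisense"` (default; the silencing-competent
#'   strand), `"sense"` or `"both"`.
#' @return Named numeric vector over all TE features.
#' @export
te_levels <- function(lib, orientation = c("antisense", "sense", "both")) {
  stopifnot(inherits(lib, "normalized_library"))
  orientation <- match.arg(orientation)
  te_ids <- .ids_of_class(lib$ref, "TE")
  al <- .pirna_rows(lib)
  al <- al[al$feature_id %in% te_ids, , drop = FALSE]
  if (orientation == "antisense") al <- al[al$strand == "-", , drop = FALSE]
  if (orientation == "sense") al <- al[al$strand == "+", , drop = FALSE]
  out <- setNames(numeric(length(te_ids)), te_ids)
  if (nrow(al)) {
    v <- tapply(al$weight * lib$factor, al$feature_id, sum)
    out[names(v)] <- v
  }
  out
}

# Global 23-30 nt (piRNA window) non-miRNA RPMM mass of a library.
.global_pirna_mass <- function(lib) {
  al <- .pirna_rows(lib)
  cls <- .row_class(al, lib$ref)
  sum(al$weight[cls != "miRNA"]) * lib$factor
}

#' Compare a knockdown library to its control
#'
#' Computes per-TE antisense piRNA levels in both libraries, per-TE
#' log2 fold changes with a pseudocount, the Pearson correlation of the
#' log2 level vectors across all TEs, the global piRNA reduction (ratio
#' of 23--30 nt non-miRNA RPMM masses, knockdown / control), and the
#' per-TE change in ping-pong z-score (`dz10 = z10(kd) - z10(control)`).
#'
#' @param control,kd `normalized_library` objects sharing a reference.
#' @param pseudocount RPMM pseudocount for the log2 transforms
#'   (default 1).
#' @param compute_z Compute per-TE overlap z-scores (default TRUE; the
#'   dominant cost).
#' @return A `library_comparison`: list with `per_te` (data.frame:
#'   te, control, kd, log2fc, z10_control, z10_kd, dz10), `pearson_r`,
#'   `global_ratio`, `pseudocount`.
#' @export
compare_libraries <- function(control, kd, pseudocount = 1,
                              compute_z = TRUE) {
  stopifnot(inherits(control, "normalized_library"),
            inherits(kd, "normalized_library"))
  if (!identical(control$ref$features$id, kd$ref$features$id))
    stop("libraries must share the reference panel")
  lv_c <- te_levels(control, "antisense")
  lv_k <- te_levels(kd, "antisense")
  c0 <- pseudocount
  log2fc <- log2((lv_k + c0) / (lv_c + c0))
  nonzero <- sum(lv_c > 0 | lv_k > 0)
  pearson_r <- if (nonzero >= 2L) {
    cor(log2(lv_c + c0), log2(lv_k + c0))
  } else {
    warning("fewer than 2 TEs with nonzero levels: Pearson r undefined")
    NA_real_
  }
  global_ratio <- .global_pirna_mass(kd) / .global_pirna_mass(control)

  per_te <- data.frame(te = names(lv_c), control = unname(lv_c),
                       kd = unname(lv_k), log2fc = unname(log2fc),
                       stringsAsFactors = FALSE)
  if (compute_z) {
    zc <- vapply(per_te$te, function(t)
      overlap_histogram(control, features = t)$z10, numeric(1))
    zk <- vapply(per_te$te, function(t)
      overlap_histogram(kd, features = t)$z10, numeric(1))
    per_te$z10_control <- unname(zc)
    per_te$z10_kd <- unname(zk)
    per_te$dz10 <- per_te$z10_kd - per_te$z10_control
  }
  rownames(per_te) <- NULL
  structure(list(per_te = per_te, pearson_r = pearson_r,
                 global_ratio = global_ratio, pseudocount = pseudocount),
            class = "library_comparison")
}

#' @export
print.library_comparison <- function(x, ...) {
  cat(sprintf(paste0("library_comparison: %d TEs, global piRNA ratio ",
                     "%.3f, Pearson r %.3f\n"),
              nrow(x$per_te), x$global_ratio, x$pearson_r))
  invisible(x)
}

#' Classify TE piRNA origin between two compartments
#'
#' Labels each TE by the log2 ratio of its piRNA levels in a soma library
#' versus a germline library: `>= log2_margin` soma-dominant,
#' `<= -log2_margin` germline-dominant, otherwise intermediate. TEs with
#' zero level in both compartments are unclassified (`NA`) with a
#' warning.
#'
#' @param soma_levels,germline_levels Named per-TE levels in common RPMM
#'   units.
#' @param log2_margin Margin in log2 units (default 1).
#' @return Character vector of classes (`"soma-dominant"`,
#'   `"intermediate"`, `"germline-dominant"`, or `NA`), named by TE.
#' @export
classify_te_origin <- function(soma_levels, germline_levels,
                               log2_margin = 1) {
  stopifnot(length(soma_levels) == length(germline_levels))
  lr <- log2(soma_levels / germline_levels)
  out <- rep("intermediate", length(lr))
  out[lr >= log2_margin] <- "soma-dominant"
  out[lr <= -log2_margin] <- "germline-dominant"
  both0 <- soma_levels == 0 & germline_levels == 0
  if (any(both0)) {
    warning(sum(both0), " TE(s) with zero levels in both compartments ",
            "left unclassified")
    out[both0] <- NA_character_
  }
  setNames(out, names(soma_levels))
}

#' Type I biogenesis-factor signature per TE
#'
#' Loss of a type I primary biogenesis factor (Zuc/Armi-like) collapses
#' piRNA levels for most TEs, while TEs produced almost exclusively via
#' ping-pong keep their levels and show a strengthened 10-nt overlap
#' signature. This labels each TE accordingly: `"collapsed"` when
#' `log2fc <= -fc_threshold`; `"pingpong-rescued"` when the level did not
#' collapse and `dz10 >= dz_threshold`; otherwise `"unchanged"`. TEs with
#' zero level in both libraries are skipped (`NA`).
#'
#' @param comparison A `library_comparison` computed with per-TE z-scores.
#' @param fc_threshold Collapse threshold in log2 units (default 2, i.e.
#'   a 4-fold drop).
#' @param dz_threshold Ping-pong strengthening threshold in z units
#'   (default 2).
#' @return Character vector of labels, named by TE.
#' @export
typeI_signature <- function(comparison, fc_threshold = 2,
                            dz_threshold = 2) {
  stopifnot(inherits(comparison, "library_comparison"))
  pt <- comparison$per_te
  if (is.null(pt$dz10))
    stop("comparison lacks per-TE z-scores; rerun compare_libraries() ",
         "with compute_z = TRUE")
  lab <- ifelse(pt$log2fc <= -fc_threshold, "collapsed",
         ifelse(pt$dz10 >= dz_threshold, "pingpong-rescued", "unchanged"))
  lab[pt$control == 0 & pt$kd == 0] <- NA_character_
  setNames(lab, pt$te)
}
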