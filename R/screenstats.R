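#' Summarize an RNAi screen from per-line records
#'
#' Aggregates per (gene, line) staining and morphology records to
#' gene-level screen statistics: counts and percentages of genes with any
#' staining, with strong-range staining, per-morphology gene counts
#' (a gene counts for a morphology if at least one of its lines shows
#' it), and screen coverage (tested / expressed genes).
#'
#' @param records data.frame with columns `gene_id`, `line_id`,
#'   `staining` (ordinal 0--5 or labels of [staining_scale()]), and
#'   optionally `morphology` (`wild_type`, `distorted`, `rudimentary`).
#' @param tested_gene_total Total genes tested in the screen.
#' @param expressed_gene_total Total expressed genes (coverage
#'   denominator).
#' @param strong_range Staining labels counted as the strong range
#'   (default intermediate-strong and strong).
#' @return A `screen_summary` list: `n_tested`, `n_expressed`,
#'   `n_any_staining`, `pct_any_staining`, `n_strong`, `pct_strong`,
#'   `coverage_pct`, `morphology_counts`.
#' @export
summarize_screen <- function(records, tested_gene_total,
                             expressed_gene_total,
                             strong_range = c("intermediate-strong",
                                              "strong")) {
  if (tested_gene_total <= 0 || expressed_gene_total <= 0)
    stop("gene totals must be > 0")
  if (nrow(records)) {
    st <- .as_staining(records$staining)
    per_gene_max <- tapply(st, records$gene_id, max)
    n_any <- sum(per_gene_max > 0L)
    strong_vals <- .STAINING_LEVELS[strong_range]
    n_strong <- sum(per_gene_max >= min(strong_vals))
    morph <- if (!is.null(records$morphology)) {
      tab <- table(unique(records[, c("gene_id", "morphology")])$morphology)
      setNames(as.integer(tab), names(tab))
    } else integer(0)
  } else {
    n_any <- 0L; n_strong <- 0L; morph <- integer(0)
  }
  if (n_any > tested_gene_total)
    stop("more scoring genes than tested genes")
  screen_summary_from_counts(tested_gene_total, expressed_gene_total,
                             n_any, n_strong, morph)
}

#' Screen summary from gene-level totals
#'
#' Builds the same summary as [summarize_screen()] directly from printed
#' gene-level totals, for screens where only the aggregate counts are
#' available.
#'
#' @param n_tested,n_expressed,n_any_staining,n_strong Gene counts.
#' @param morphology_counts Optional named integer vector of per-category
#'   gene counts.
#' @return A `screen_summary` list.
#' @export
screen_summary_from_counts <- function(n_tested, n_expressed,
                                       n_any_staining, n_strong,
                                       morphology_counts = integer(0)) {
  if (n_tested <= 0 || n_expressed <= 0) stop("gene totals must be > 0")
  structure(list(
    n_tested = n_tested,
    n_expressed = n_expressed,
    n_any_staining = n_any_staining,
    pct_any_staining = 100 * n_any_staining / n_tested,
    n_strong = n_strong,
    pct_strong = 100 * n_strong / n_tested,
    coverage_pct = 100 * n_tested / n_expressed,
    morphology_counts = morphology_counts), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(paste0("screen_summary: %d/%d tested genes with any ",
                     "staining (%.2g%%), %d strong-range (%.2g%%), ",
                     "coverage %.0f%%\n"),
              x$n_any_staining, x$n_tested, signif(x$pct_any_staining, 2),
              x$n_strong, signif(x$pct_strong, 2), x$coverage_pct))
  invisible(x)
}

#' Published gene-level totals of the ovarian somatic piRNA screen
#'
#' The printed aggregate counts of the genome-scale Drosophila ovarian
#' somatic-cell RNAi screen analysed by this package: genes tested and
#' expressed, reporter-staining hit counts, the rudimentary-ovary
#' morphology count, the ribosomal-protein control set and its per-line
#' knockdown efficiency, and the genes tested below the expression
#' cutoff.
#'
#' @return Named list of totals.
#' @export
reported_screen_totals <- function() {
  list(tested_genes = 6818L,
       crosses = 12804L,
       expressed_genes = 7257L,
       any_staining_genes = 144L,
       strong_range_genes = 49L,
       rudimentary_genes = 663L,
       ribosomal_control_genes = 83L,
       effective_line_fraction = 0.83,
       lines_per_gene = 2L,
       below_cutoff_genes_tested = 358L)
}

#' Gene-level false-negative model for an arm-per-line screen
#'
#' With per-line knockdown efficiency `p` and `n` independent lines
#' tested per gene, the probability of missing a true factor is
#' `fn(n) = (1 - p)^n`.
#'
#' @param p Per-line efficiency in \[0,1\].
#' @param n Number of lines tested per gene.
#' @return Gene-level false-negative probability.
#' @export
detection_fn <- function(p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 0))
  (1 - p)^n
}

#' Estimate screen detection efficiency from control knockdowns
#'
#' Given per-line phenotype calls for a control gene set with an expected
#' knockdown phenotype (e.g. ribosomal-protein genes, whose effective
#' knockdown produces rudimentary ovaries), estimates the per-line
#' efficiency `p` as the fraction of effective lines and reports the
#' model gene-level false-negative rate `fn(n) = (1 - p)^n` alongside the
#' empirical gene-level miss rate (fraction of control genes with no
#' effective line).
#'
#' @param control_records data.frame with columns `gene_id`, `line_id`
#'   and `effective` (logical).
#' @param n_lines Lines per gene assumed by the model (default 2).
#' @return A `detection_model` list: `p`, `n_lines`, `model_fn`,
#'   `empirical_fn`, `fn` (function of n).
#' @export
estimate_detection <- function(control_records, n_lines = 2L) {
  if (!nrow(control_records)) stop("empty control record set")
  stopifnot(all(c("gene_id", "effective") %in% names(control_records)))
  eff <- as.logical(control_records$effective)
  p <- mean(eff)
  per_gene_miss <- tapply(eff, control_records$gene_id,
                          function(e) !any(e))
  structure(list(p = p, n_lines = n_lines,
                 model_fn = detection_fn(p, n_lines),
                 empirical_fn = mean(per_gene_miss),
                 fn = function(n) detection_fn(p, n)),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(paste0("detection_model: per-line efficiency %.1f%%, ",
                     "model FN(%d lines) %.1f%%, empirical FN %.1f%%\n"),
              100 * x$p, x$n_lines, 100 * x$model_fn,
              100 * x$empirical_fn))
  invisible(x)
}

#' Phenotype rates across expression bins
#'
#' Ranks expressed genes (`rpkm > cutoff`) by expression, cuts them into
#' `n_bins` equal-size bins (bin 1 lowest, bin `n_bins` highest; the
#' division remainder goes to the top bin), assigns genes at or below the
#' cutoff to bin 0, and reports the per-bin percentage of genes flagged
#' with each phenotype.
#'
#' @param records data.frame with columns `gene_id` and `phenotype`
#'   (character); a gene may carry several phenotype rows.
#' @param expression_table data.frame with columns `gene_id` and `rpkm`
#'   covering every gene to be binned (tested genes without a phenotype
#'   record count in the denominator).
#' @param n_bins Number of expression bins (default 10).
#' @param cutoff Expression cutoff separating bin 0 (default 1).
#' @return data.frame with columns `bin`, `n_genes`, `phenotype`,
#'   `n_flagged`, `pct`.
#' @export
phenotype_by_bin <- function(records, expression_table, n_bins = 10L,
                             cutoff = 1) {
  stopifnot(all(c("gene_id", "rpkm") %in% names(expression_table)))
  et <- expression_table[!duplicated(expression_table$gene_id), ]
  expressed <- et[et$rpkm > cutoff, ]
  n <- nrow(expressed)
  if (n_bins > n) stop("more bins than expressed genes")
  ord <- order(expressed$rpkm)
  size <- n %/% n_bins
  bin <- pmin((seq_len(n) - 1L) %/% size + 1L, n_bins)  # remainder -> top
  bins <- setNames(rep(0L, nrow(et)), et$gene_id)
  bins[expressed$gene_id[ord]] <- bin

  phenos <- unique(records$phenotype)
  out <- list()
  for (b in sort(unique(bins))) {
    genes_b <- names(bins)[bins == b]
    for (ph in phenos) {
      flagged <- unique(records$gene_id[records$phenotype == ph])
      nf <- sum(genes_b %in% flagged)
      out[[length(out) + 1L]] <- data.frame(
        bin = b, n_genes = length(genes_b), phenotype = ph,
        n_flagged = nf, pct = 100 * nf / length(genes_b),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Box-plot statistics and rank tests for fold-change groups
#'
#' For each group of fold-change values (e.g. RT-qPCR fold changes of
#' RNAi lines grouped by staining category): median, quartiles, whiskers
#' at 1.5 interquartile ranges, outliers beyond the whiskers, and a
#' two-sided Wilcoxon rank test against the reference group.
#'
#' @param fc_table data.frame with columns `value` and `group`.
#' @param reference_group Group name used as the test reference (e.g.
#'   control lines).
#' @param paired Use the paired signed-rank variant (default FALSE:
#'   unpaired rank-sum).
#' @return data.frame per group: `group`, `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`, `p_vs_reference`.
#' @export
group_fold_changes <- function(fc_table, reference_group,
                               paired = FALSE) {
  stopifnot(all(c("value", "group") %in% names(fc_table)))
  groups <- unique(as.character(fc_table$group))
  if (!reference_group %in% groups)
    stop("reference group '", reference_group, "' missing from table")
  ref <- fc_table$value[fc_table$group == reference_group]
  out <- lapply(groups, function(g) {
    v <- fc_table$value[fc_table$group == g]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    p <- if (g == reference_group) NA_real_ else
      suppressWarnings(wilcox.test(v, ref, paired = paired,
                                   exact = FALSE)$p.value)
    data.frame(group = g, n = length(v), median = q[2], q1 = q[1],
               q3 = q[3], whisker_lo = lo, whisker_hi = hi,
               n_outliers = sum(v < lo | v > hi),
               p_vs_reference = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify pathway specificity from two-reporter staining
#'
#' Combines a gene's soma-reporter and germline-reporter staining scores
#' into a pathway-specificity class: at or above `threshold` in both
#' compartments is `"common"`, in exactly one is that compartment's
#' specific class, and a gene whose germline (or soma) assay is not
#' interpretable (NA score) is `"not-interpretable"`. Genes below
#' threshold in both assays return `"none"`.
#'
#' @param soma_score,germline_score Staining scores (ordinal 0--5,
#'   labels, or NA for not assayable); vectorized.
#' @param threshold Inclusion threshold (default `"weak-intermediate"`).
#' @return Character vector of classes.
#' @export
classify_pathway_specificity <- function(soma_score, germline_score,
                                         threshold = "weak-intermediate") {
  s <- .as_staining(soma_score)
  g <- .as_staining(germline_score)
  stopifnot(length(s) == length(g))
  t0 <- .as_staining(threshold)
  out <- character(length(s))
  na <- is.na(s) | is.na(g)
  out[na] <- "not-interpretable"
  hs <- !na & s >= t0
  hg <- !na & g >= t0
  out[hs & hg] <- "common"
  out[hs & !hg] <- "soma-specific"
  out[!hs & hg & !na] <- "germline-specific"
  out[!na & !hs & !hg] <- "none"
  out
}
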