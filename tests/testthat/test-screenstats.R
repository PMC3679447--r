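test_that("screen summary percentages follow the printed-count arithmetic", {
  tot <- reported_screen_totals()
  s <- screen_summary_from_counts(tot$tested_genes, tot$expressed_genes,
                                  tot$any_staining_genes,
                                  tot$strong_range_genes)
  expect_equal(signif(s$pct_any_staining, 1), 2)
  expect_equal(signif(s$pct_strong, 1), 0.7)
  expect_equal(round(s$coverage_pct), 94)
  expect_error(screen_summary_from_counts(0, 10, 0, 0), "> 0")
})

test_that("record-level summary tallies genes, not lines", {
  rec <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g4"),
    line_id = c("l1", "l2", "l3", "l4", "l5", "l6"),
    staining = c("none", "strong", "weak", "none", "none",
                 "intermediate-strong"),
    morphology = c("wild_type", "distorted", "wild_type", "wild_type",
                   "rudimentary", "wild_type"),
    stringsAsFactors = FALSE)
  s <- summarize_screen(rec, tested_gene_total = 10,
                        expressed_gene_total = 20)
  expect_equal(s$n_any_staining, 3L)     # g1, g2, g4
  expect_equal(s$n_strong, 2L)           # g1 (strong), g4
  expect_equal(s$pct_any_staining, 30)
  expect_equal(unname(s$morphology_counts["rudimentary"]), 1L)
  # an independent tally over the raw records agrees
  manual_any <- sum(tapply(.subset2(rec, "staining") != "none",
                           rec$gene_id, any))
  expect_equal(s$n_any_staining, manual_any)
  # empty screens report zero percentages
  s0 <- summarize_screen(rec[0, ], 10, 20)
  expect_equal(s0$pct_any_staining, 0)
  expect_equal(s0$pct_strong, 0)
})

test_that("detection model matches brute-force enumeration of line outcomes", {
  p <- 0.83
  expect_equal(detection_fn(1, 3), 0)
  expect_equal(detection_fn(p, 1), 0.17)
  expect_equal(detection_fn(p, 2), 0.0289)
  # enumerate all 2^n outcome vectors; miss = no effective line
  for (n in 1:4) {
    outcomes <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    pr <- apply(outcomes, 1, function(o)
      prod(ifelse(o, p, 1 - p)))
    miss <- apply(outcomes, 1, function(o) !any(o))
    expect_equal(detection_fn(p, n), sum(pr[miss]))
    # strictly decreasing in n
    if (n > 1) expect_lt(detection_fn(p, n), detection_fn(p, n - 1))
  }
})

test_that("detection estimation reports model and empirical miss rates", {
  # 4 control genes x 2 lines; g4 has no effective line
  rec <- data.frame(
    gene_id = rep(c("g1", "g2", "g3", "g4"), each = 2),
    line_id = sprintf("l%d", 1:8),
    effective = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  dm <- estimate_detection(rec, n_lines = 2L)
  expect_equal(dm$p, 0.5)
  expect_equal(dm$model_fn, 0.25)
  expect_equal(dm$empirical_fn, 0.25)
  expect_equal(dm$fn(3), 0.125)
  expect_error(estimate_detection(rec[0, ]), "empty")
})

test_that("expression-bin phenotype rates follow rank binning", {
  # 20 genes, 2 bins, phenotype only among the top-10 expressed
  et <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   rpkm = seq(2, 40, by = 2), stringsAsFactors = FALSE)
  rec <- data.frame(gene_id = sprintf("g%02d", 11:20),
                    phenotype = "hit", stringsAsFactors = FALSE)
  pb <- phenotype_by_bin(rec, et, n_bins = 2L)
  expect_equal(pb$pct[pb$bin == 1], 0)
  expect_equal(pb$pct[pb$bin == 2], 100)

  # below-cutoff genes land in bin 0
  et2 <- rbind(et, data.frame(gene_id = "low1", rpkm = 0.5))
  pb2 <- phenotype_by_bin(rec, et2, n_bins = 2L)
  expect_true(0 %in% pb2$bin)
  expect_equal(pb2$n_genes[pb2$bin == 0], 1L)
  expect_error(phenotype_by_bin(rec, et, n_bins = 50L), "more bins")

  # all genes flagged -> every bin at 100%
  rec_all <- data.frame(gene_id = et$gene_id, phenotype = "hit",
                        stringsAsFactors = FALSE)
  pb3 <- phenotype_by_bin(rec_all, et, n_bins = 4L)
  expect_true(all(pb3$pct == 100))

  # uniform random phenotype: per-bin rates near the global rate
  set.seed(77)
  n <- 6820
  etr <- data.frame(gene_id = sprintf("g%05d", 1:n),
                    rpkm = rlnorm(n, 2, 1.5), stringsAsFactors = FALSE)
  flagged <- etr$gene_id[runif(n) < 0.3]
  recr <- data.frame(gene_id = flagged, phenotype = "hit",
                     stringsAsFactors = FALSE)
  pbr <- phenotype_by_bin(recr, etr, n_bins = 10L)
  pbr <- pbr[pbr$bin > 0, ]
  se <- sqrt(0.3 * 0.7 / pbr$n_genes)
  expect_true(all(abs(pbr$pct / 100 - 0.3) < 3.5 * se))
})

test_that("fold-change groups report box statistics and rank-test p values", {
  # identical group vs reference: p ~ 1
  tab <- data.frame(value = c(1:10, 1:10),
                    group = rep(c("ref", "g"), each = 10),
                    stringsAsFactors = FALSE)
  g <- group_fold_changes(tab, "ref")
  expect_gt(g$p_vs_reference[g$group == "g"], 0.9)
  expect_true(is.na(g$p_vs_reference[g$group == "ref"]))

  # {1,2,3,4,100}: median 3, 100 flagged by the 1.5 IQR rule
  tab2 <- data.frame(value = c(1, 2, 3, 4, 100, 1, 2, 3),
                     group = c(rep("g", 5), rep("ref", 3)),
                     stringsAsFactors = FALSE)
  g2 <- group_fold_changes(tab2, "ref")
  row <- g2[g2$group == "g", ]
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
  expect_equal(row$n_outliers, 1L)

  # a clearly shifted group is detected at n = 30
  set.seed(13)
  tab3 <- data.frame(
    value = c(rnorm(30, 1, 0.3), rnorm(30, 2.5, 0.3)),
    group = rep(c("ref", "up"), each = 30), stringsAsFactors = FALSE)
  g3 <- group_fold_changes(tab3, "ref")
  expect_lt(g3$p_vs_reference[g3$group == "up"], 0.01)
  expect_error(group_fold_changes(tab3, "missing"), "missing")
})

test_that("pathway specificity classes combine the two reporters", {
  expect_equal(classify_pathway_specificity(5, 0), "soma-specific")
  expect_equal(classify_pathway_specificity(3, 3), "common")
  expect_equal(classify_pathway_specificity(0, 4), "germline-specific")
  expect_equal(classify_pathway_specificity(2, NA), "not-interpretable")
  expect_equal(classify_pathway_specificity(1, 1), "none")
  expect_equal(
    classify_pathway_specificity(c("strong", "intermediate"),
                                 c("none", "weak-intermediate")),
    c("soma-specific", "common"))
  expect_error(classify_pathway_specificity(7, 0), "0..5")
  expect_error(classify_pathway_specificity("blazing", 0), "unknown")
})
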