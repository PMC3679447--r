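test_that("config validation rejects impossible settings", {
  expect_error(sim_config(te_length_range = c(500L, 100L)), "degenerate")
  expect_error(sim_config(u1_bias = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(pingpong_fraction = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(n_te = 0L), ">= 1")
  expect_error(sim_config(pirna_length_bounds = c(10L, 30L)),
               "\\[18, 35\\]")
  # fragment longer than any source TE is impossible
  cfg <- sim_config(n_te = 1L, te_length_range = c(100L, 100L),
                    fragment_length_range = c(150L, 150L),
                    cluster_spec = list(list(id = "c1",
                                             strand_mode = "uni",
                                             fragment_count = 2L)),
                    seed = 1L)
  expect_error(build_reference(cfg), "exceeds source TE")
})

test_that("uni-strand clusters carry only antisense fragments and dual both", {
  cfg <- sim_config(n_te = 2L, te_length_range = c(600L, 900L),
                    cluster_spec = list(
                      list(id = "uni", strand_mode = "uni",
                           fragment_count = 6L),
                      list(id = "dual", strand_mode = "dual",
                           fragment_count = 40L)),
                    seed = 7L)
  ref <- build_reference(cfg)
  fr <- ref$fragments
  expect_true(all(fr$strand[fr$cluster_id == "uni"] == "-"))
  expect_setequal(unique(fr$strand[fr$cluster_id == "dual"]),
                  c("+", "-"))
  # fragment coordinates are 0-based half-open and tile each cluster
  for (cl in c("uni", "dual")) {
    f <- fr[fr$cluster_id == cl, ]
    expect_equal(f$start0[1], 0L)
    expect_equal(f$end0[nrow(f)],
                 ref$features$length[ref$features$id == cl])
    expect_equal(f$start0[-1], f$end0[-nrow(f)])
  }
  # fragment sequences really come from their source TEs
  for (k in seq_len(6)) {
    f <- fr[k, ]
    frag <- substr(as.character(ref$seqs[[f$cluster_id]]),
                   f$start0 + 1L, f$end0)
    src <- substr(as.character(ref$seqs[[f$source_te]]),
                  f$te_start0 + 1L, f$te_start0 + (f$end0 - f$start0))
    if (f$strand == "-")
      src <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(src)))
    expect_identical(frag, src)
  }
})

test_that("identical (config, seed) pairs reproduce byte-identical output", {
  cfg <- small_config(seed = 11L, depth = 5000L)
  ref1 <- build_reference(cfg)
  ref2 <- build_reference(cfg)
  expect_identical(as.character(ref1$seqs), as.character(ref2$seqs))
  expect_identical(ref1$fragments, ref2$fragments)
  s1 <- simulate_library(ref1, cfg)
  s2 <- simulate_library(ref2, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_knockdown_pair(ref1, cfg)
  p2 <- simulate_knockdown_pair(ref1, cfg)
  expect_identical(p1, p2)
})

test_that("emitted read totals equal the sum of truth class masses", {
  for (seed in c(3L, 4L)) {
    cfg <- small_config(seed = seed, depth = 8000L)
    ref <- build_reference(cfg)
    sim <- simulate_library(ref, cfg)
    expect_identical(sum(sim$reads$count),
                     as.integer(sum(sim$truth$class_masses)))
    expect_identical(sim$truth$total_reads,
                     sum(sim$truth$class_masses))
  }
})

test_that("zero depth yields an empty library, not an error", {
  cfg <- small_config(seed = 5L, depth = 0L)
  ref <- build_reference(cfg)
  sim <- simulate_library(ref, cfg)
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(unname(sim$truth$class_masses),
               c(0, 0, 0))
})

test_that("phi = 0 disables the ping-pong arm", {
  cfg <- te_only_config(seed = 9L, phi = 0)
  ref <- build_reference(cfg)
  sim <- simulate_library(ref, cfg)
  expect_equal(sum(sim$truth$per_te_pingpong), 0)
  expect_equal(unname(sim$truth$class_masses["pingpong"]), 0)
})

test_that("phi for a TE absent from the reference is rejected", {
  cfg <- te_only_config(seed = 9L)
  cfg$pingpong_fraction <- c(te99 = 0.5)
  ref <- build_reference(te_only_config(seed = 9L))
  expect_error(simulate_library(ref, cfg), "absent")
})

test_that("u1_bias = 1 forces every primary piRNA to start with U", {
  cfg <- te_only_config(seed = 13L, depth = 10000L, u1_bias = 1)
  ref <- build_reference(cfg)
  sim <- simulate_library(ref, cfg)
  # primary reads are the non-miRNA reads here (phi = 0)
  mir <- as.character(ref$seqs[.subset2(ref, "features")$class == "miRNA"])
  prim <- sim$reads[!sim$reads$sequence %in% mir, ]
  expect_gt(nrow(prim), 100)
  expect_true(all(substr(prim$sequence, 1, 1) == "T"))
})

test_that("observed 1U fraction converges to u1_bias (binomial tolerance)", {
  beta <- 0.7
  cfg <- te_only_config(seed = 17L, depth = 100000L, u1_bias = beta)
  ref <- build_reference(cfg)
  sim <- simulate_library(ref, cfg)
  mir <- as.character(ref$seqs[ref$features$class == "miRNA"])
  prim <- sim$reads[!sim$reads$sequence %in% mir, ]
  n <- sum(prim$count)
  obs <- sum(prim$count[substr(prim$sequence, 1, 1) == "T"]) / n
  se <- sqrt(beta * (1 - beta) / n)
  expect_lt(abs(obs - beta), 3 * se)
})

test_that("responder 10A fraction equals initiator 1U fraction exactly", {
  for (seed in c(21L, 22L)) {
    cfg <- small_config(seed = seed, phi = 0.5, depth = 20000L)
    ref <- build_reference(cfg)
    sim <- simulate_library(ref, cfg)
    expect_gt(sim$truth$pingpong_pairs, 0)
    expect_identical(sim$truth$initiator_u1_fraction,
                     sim$truth$responder_a10_fraction)
  }
})

test_that("knockdown pair: r = 1 leaves expectations equal, r = 0 removes primary", {
  cfg <- small_config(seed = 31L, phi = 0.4, depth = 20000L,
                      primary_reduction = 1)
  ref <- build_reference(cfg)
  pair <- simulate_knockdown_pair(ref, cfg)
  tc <- pair$truth$control$class_masses
  tk <- pair$truth$knockdown$class_masses
  # equal expectation: Poisson difference within 5 sd of the pair
  expect_lt(abs(tk["primary"] - tc["primary"]),
            5 * sqrt(tc["primary"] + tk["primary"]))

  cfg0 <- small_config(seed = 31L, phi = 0.4, depth = 20000L,
                       primary_reduction = 0)
  pair0 <- simulate_knockdown_pair(ref, cfg0)
  expect_equal(unname(pair0$truth$knockdown$class_masses["primary"]), 0)
  expect_gt(unname(pair0$truth$knockdown$class_masses["pingpong"]), 0)
  expect_error(
    simulate_knockdown_pair(ref, within_cfg <- {
      c2 <- cfg; c2$primary_reduction <- 1.5; c2
    }), "\\[0, 1\\]")
})
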