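test_that("consensus BPS calling applies focal, support and dual-aligner criteria", {
  thr <- calling_thresholds(min_depth = 1)
  focal <- counts_row(C = 48, c = 50)         # consensus C, 48F/50R
  others <- match("T", c("A", "C", "G", "T")) # other lines agree on T
  call <- call_bps(focal, focal, others, thr)
  expect_equal(nrow(call), 1L)
  expect_equal(call$ref, "T")
  expect_equal(call$alt, "C")

  # 50/50 split: no base reaches the 80% focal consensus
  amb <- counts_row(C = 25, c = 25, T = 25, t = 25)
  expect_equal(nrow(call_bps(amb, amb, others, thr)), 0L)

  # aligners disagree on the alternate base: no call
  a1 <- counts_row(C = 48, c = 50)
  a2 <- counts_row(A = 48, a = 50)
  expect_equal(nrow(call_bps(a1, a2, others, thr)), 0L)

  # focal base equals the others' consensus: no mutation
  same <- counts_row(T = 40, t = 40)
  expect_equal(nrow(call_bps(same, same, others, thr)), 0L)

  # support below 2 forward reads: rejected
  weak <- counts_row(C = 1, c = 80)
  expect_equal(nrow(call_bps(weak, weak, others, thr)), 0L)

  expect_error(call_bps(focal, focal, NA_integer_, thr), "empty")
})

test_that("consensus indel criteria: fraction, strand support, dual aligner", {
  thr <- calling_thresholds()
  ev <- one_evidence(fwd = 2L, rev = 2L, spanning = 10L)  # 40% >= 30%
  expect_equal(nrow(call_indels_consensus(ev, ev, thr)), 1L)

  lop <- one_evidence(fwd = 1L, rev = 3L, spanning = 10L)
  expect_equal(nrow(call_indels_consensus(lop, lop, thr)), 0L)

  dilute <- one_evidence(fwd = 2L, rev = 2L, spanning = 20L)  # 20% < 30%
  expect_equal(nrow(call_indels_consensus(dilute, dilute, thr)), 0L)

  expect_equal(nrow(call_indels_consensus(ev, empty_evidence(), thr)), 0L)

  # same position but different motif is not the same indel
  other <- one_evidence(motif = "GT")
  expect_equal(nrow(call_indels_consensus(ev, other, thr)), 0L)
})

test_that("large-indel criteria: 6F/6R and 20 supporting reads overall", {
  thr <- calling_thresholds()
  big <- one_evidence(type = "deletion", size = 12581L, motif = "",
                      fwd = 10L, rev = 10L, spanning = 40L,
                      source = "paired-evidence")
  expect_equal(nrow(call_indels_large(big, thr)), 1L)

  few <- one_evidence(fwd = 6L, rev = 6L, spanning = 40L,
                      source = "paired-evidence")
  expect_equal(nrow(call_indels_large(few, thr)), 0L)   # 12 < 20 total

  skew <- one_evidence(fwd = 5L, rev = 15L, spanning = 40L,
                       source = "paired-evidence")
  expect_equal(nrow(call_indels_large(skew, thr)), 0L)  # fwd < 6
})

test_that("progenitor filter removes events shared by a strict majority", {
  shared24 <- do.call(rbind, lapply(1:24, function(li)
    catalog_row(line = li, pos = 500L)))
  shared23 <- do.call(rbind, lapply(1:23, function(li)
    catalog_row(line = li, pos = 900L, alt = "G", ref = "A")))
  unique1 <- catalog_row(line = 5L, pos = 1300L)
  cat <- rbind(shared24, shared23, unique1)
  kept <- filter_progenitor(cat, n_lines = 47)
  expect_equal(sum(kept$pos == 500L), 0L)    # 24/47 > 50%: removed
  expect_equal(sum(kept$pos == 900L), 23L)   # 23/47 < 50%: retained
  expect_equal(sum(kept$pos == 1300L), 1L)
})

test_that("raising thresholds never increases the number of calls", {
  g <- generate_reference(20000, 0.5, 0, seed = 21)
  cfg <- sim_config(n_lines = 6, n_bps = 30, n_insertions = 6,
                    n_deletions = 6, coverage_mean = 40,
                    error_rate = 0.02, indel_sizes = 1:3, seed = 22)
  sim <- simulate_counts(g, plant_mutations(g, cfg), cfg)
  base <- nrow(call_catalog(sim, calling_thresholds())$catalog)
  harder <- list(
    calling_thresholds(focal_frac = 0.9),
    calling_thresholds(min_fwd = 5L, min_rev = 5L),
    calling_thresholds(indel_frac = 0.6),
    calling_thresholds(min_depth = 30L),
    calling_thresholds(indel_min_fwd = 10L, indel_min_rev = 10L))
  for (thr in harder) {
    expect_lte(nrow(call_catalog(sim, thr)$catalog), base)
  }
})

test_that("relabelling lines permutes but does not change the catalog", {
  g <- generate_reference(10000, 0.5, 0, seed = 31)
  cfg <- sim_config(n_lines = 5, n_bps = 20, n_insertions = 4,
                    n_deletions = 4, seed = 32)
  sim <- simulate_counts(g, plant_mutations(g, cfg), cfg)
  res <- call_catalog(sim)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  res_p <- call_catalog(sim[perm])
  a <- res$catalog
  b <- res_p$catalog
  b$line <- perm[b$line]                # map permuted ids back
  b <- b[order(b$line, b$pos), ]
  rownames(b) <- NULL
  a <- a[order(a$line, a$pos), ]
  rownames(a) <- NULL
  expect_equal(a, b)
})
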