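test_that("reference generation is deterministic and honours its knobs", {
  g1 <- generate_reference(1000, 0.5, 0.5, seed = 7)
  g2 <- generate_reference(1000, 0.5, 0.5, seed = 7)
  expect_identical(g1$bases, g2$bases)
  expect_identical(g1$genes, g2$genes)

  g0 <- generate_reference(300, 0.5, 0, seed = 1)
  expect_equal(nrow(g0$genes), 0L)

  g <- generate_reference(1e5, 0.6, 0.3, seed = 2)
  gc <- mean(g$bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.6), 3 * sqrt(0.6 * 0.4 / 1e5))
  # gene lengths are codon-sized and genes do not overlap
  expect_true(all((g$genes$end - g$genes$start + 1L) %% 3L == 0L))
  ord <- order(g$genes$start)
  expect_true(all(diff(g$genes$start[ord]) >
                    (g$genes$end - g$genes$start)[ord][-nrow(g$genes)]))

  expect_error(generate_reference(100, 0.5, 0.5), "length")
  expect_error(generate_reference(1000, 1.2, 0.5), "gc_content")
})

test_that("planted mutations match configured totals and constraints", {
  g <- generate_reference(5000, 0.5, 0, seed = 4)
  cfg <- sim_config(n_lines = 1, n_bps = 10, n_insertions = 0,
                    n_deletions = 0, seed = 3)
  tr <- plant_mutations(g, cfg)
  expect_equal(nrow(tr), 10L)
  expect_true(all(tr$type == "BPS"))
  expect_true(all(tr$ref != tr$alt))
  expect_true(all(tr$ref == g$bases[tr$pos]))
  expect_false(anyDuplicated(tr[c("line", "pos")]) > 0)

  cfg2 <- sim_config(n_lines = 4, n_bps = 30, n_insertions = 5,
                     n_deletions = 5, n_clustered_pairs = 3,
                     cluster_window = 50, seed = 8)
  tr2 <- plant_mutations(g, cfg2)
  expect_equal(sum(tr2$type == "BPS"), 30L + 3L)  # partners add events
  expect_equal(sum(tr2$type == "insertion"), 5L)
  expect_equal(sum(tr2$type == "deletion"), 5L)
  cl <- detect_mnm(tr2, 50, g$length)
  expect_gte(sum(cl$size >= 2), 3L)

  expect_error(plant_mutations(g, sim_config(n_bps = 6000, seed = 1)),
               "exceeds genome size")
})

test_that("simulated pileups follow the coverage and error model", {
  g <- generate_reference(2000, 0.5, 0, seed = 5)
  cfg0 <- sim_config(n_lines = 1, coverage_mean = 100, error_rate = 0,
                     n_bps = 0, n_insertions = 0, n_deletions = 0,
                     seed = 6)
  tr0 <- plant_mutations(g, cfg0)
  sim0 <- simulate_counts(g, tr0, cfg0)
  m <- sim0[[1]]$counts1
  tot <- m[, c(1, 3, 5, 7)] + m[, c(2, 4, 6, 8)]
  idx <- match(g$bases, c("A", "C", "G", "T"))
  expect_equal(rowSums(tot), tot[cbind(seq_len(nrow(tot)), idx)])

  g2 <- generate_reference(1e5, 0.5, 0, seed = 5)
  cfg <- sim_config(n_lines = 1, coverage_mean = 60, error_rate = 0.01,
                    n_bps = 0, n_insertions = 0, n_deletions = 0,
                    seed = 6)
  sim <- simulate_counts(g2, plant_mutations(g2, cfg), cfg)
  m <- sim[[1]]$counts1
  tot <- m[, c(1, 3, 5, 7)] + m[, c(2, 4, 6, 8)]
  idx <- match(g2$bases, c("A", "C", "G", "T"))
  depth <- rowSums(tot)
  nonref <- depth - tot[cbind(seq_len(nrow(tot)), idx)]
  frac <- sum(nonref) / sum(depth)
  se <- sqrt(0.01 * 0.99 / sum(depth))
  expect_lt(abs(frac - 0.01), 3 * se)
})

test_that("simulation is seed-deterministic", {
  g <- generate_reference(1000, 0.5, 0, seed = 1)
  cfg <- sim_config(n_lines = 2, n_bps = 5, n_insertions = 2,
                    n_deletions = 2, seed = 42)
  tr <- plant_mutations(g, cfg)
  expect_identical(tr, plant_mutations(g, cfg))
  s1 <- simulate_counts(g, tr, cfg)
  s2 <- simulate_counts(g, tr, cfg)
  expect_identical(s1, s2)
})

test_that("full aligner discordance kills consensus indel calls", {
  g <- generate_reference(5000, 0.5, 0, seed = 2)
  cfg <- sim_config(n_lines = 4, n_bps = 0, n_insertions = 5,
                    n_deletions = 5, aligner_discordance = 1,
                    indel_sizes = 1:3, seed = 9)
  tr <- plant_mutations(g, cfg)
  sim <- simulate_counts(g, tr, cfg)
  res <- call_catalog(sim)
  expect_equal(nrow(res$catalog), 0L)
})
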