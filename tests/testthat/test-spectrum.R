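test_that("BPS classification: class, transition and A/T-ward flags", {
  ga <- classify_bps("G", "A")
  expect_equal(ga$class, "G:C->A:T")
  expect_true(ga$transition)
  expect_true(ga$at_ward)

  ac <- classify_bps("A", "C")
  expect_equal(ac$class, "A:T->C:G")
  expect_false(ac$transition)
  expect_false(ac$at_ward)

  cg <- classify_bps("C", "G")
  expect_equal(cg$class, "G:C->C:G")
  expect_false(cg$transition)
  expect_false(cg$at_ward)   # G/C to G/C is not toward A/T

  expect_error(classify_bps("A", "A"), "differ")
  expect_error(classify_bps("N", "A"), "A/C/G/T")
})

test_that("classification is strand symmetric", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  fwd <- classify_bps(pairs$ref, pairs$alt)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev <- classify_bps(comp[pairs$ref], comp[pairs$alt])
  expect_equal(fwd$class, rev$class)
  expect_equal(fwd$transition, rev$transition)
  expect_equal(fwd$at_ward, rev$at_ward)
})

test_that("spectrum summary tallies classes, sizes and nucleotide turnover", {
  cat <- rbind(catalog_row(pos = 10L, ref = "G", alt = "A"),
               catalog_row(pos = 20L, ref = "A", alt = "G"),
               catalog_row(pos = 30L, ref = "C", alt = "A"),
               catalog_row(pos = 40L, type = "deletion", ref = "",
                           alt = "", size = 5L, motif = "AAAAA"),
               catalog_row(pos = 50L, type = "insertion", ref = "",
                           alt = "", size = 4L, motif = "GGGG"))
  s <- summarize_spectrum(cat, 100)   # one line, T = 100
  expect_equal(s$n_bps, 3L)
  expect_equal(s$transitions, 2L)
  expect_equal(s$at_ward, 2L)
  expect_equal(s$ts_tv_pooled, 2)
  expect_equal(s$nt_lost_per_gen, 0.05)
  expect_equal(s$nt_gained_per_gen, 0.04)
  expect_equal(s$short_deletions, 0L)
  expect_equal(s$long_insertions, 1L)
  expect_equal(sum(s$class_counts), s$n_bps)

  # no transversions: ratio flagged undefined, not infinite
  ts_only <- catalog_row(ref = "G", alt = "A")
  s2 <- summarize_spectrum(ts_only, 100)
  expect_false(s2$ts_tv_defined)
  expect_true(is.na(s2$ts_tv_pooled))
})

test_that("conditional rates divide by source base-pair content", {
  s <- list(class_counts = c(0L, 4L, 0L, 0L, 0L, 0L))
  g <- ma_genome(rep(c("G", "C", "A", "T"), c(500, 500, 400, 400)))
  r <- conditional_rates(s, g, 100)
  expect_equal(unname(r[["G:C->A:T"]]), 4 / (1000 * 100))
  expect_equal(unname(r[["A:T->G:C"]]), 0)

  # equal counts: the A:T-sourced rate is higher by the GC/AT site ratio
  s2 <- list(class_counts = c(6L, 6L, 0L, 0L, 0L, 0L))
  g2 <- ma_genome(rep(c("G", "C", "A", "T"), c(300, 300, 200, 200)))
  r2 <- conditional_rates(s2, g2, 10)
  expect_equal(unname(r2[["A:T->G:C"]] / r2[["G:C->A:T"]]), 1.5)
})

test_that("chi-square GOF matches stats::chisq.test on random tables", {
  o <- c(73, 33)
  res <- chi_square_gof(o, c(53, 53))
  expect_equal(res$statistic, 2 * 20^2 / 53)
  expect_equal(res$df, 1L)
  expect_equal(chi_square_gof(c(5, 5), c(5, 5))$statistic, 0)
  expect_equal(chi_square_gof(c(10, 0), c(5, 5))$statistic, 10)
  expect_error(chi_square_gof(c(1, 2), c(0, 3)), "positive")

  set.seed(13)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    obs <- rpois(k, 30)
    p <- runif(k); p <- p / sum(p)
    exp <- sum(obs) * p
    mine <- chi_square_gof(obs, exp)
    ref <- suppressWarnings(chisq.test(obs, p = p))
    expect_equal(mine$statistic, unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("per-line Ts/Tv handles transversion-free lines", {
  cat <- rbind(catalog_row(line = 1L, pos = 10L, ref = "G", alt = "A"),
               catalog_row(line = 1L, pos = 20L, ref = "C", alt = "T"),
               catalog_row(line = 2L, pos = 30L, ref = "G", alt = "A"),
               catalog_row(line = 2L, pos = 40L, ref = "G", alt = "T"))
  tt <- ts_tv_by_line(cat, 2L)
  expect_true(is.na(tt$ts_tv[1]))
  expect_equal(tt$ts_tv[2], 1)
})
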