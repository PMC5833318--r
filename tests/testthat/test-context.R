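test_that("coding/noncoding test uses site-proportional expectations", {
  # 1000-bp genome, 900 coding sites -> expectation 90/10 for 100 BPSs
  bases <- rep(c("A", "C", "G", "T"), 250)
  g <- ma_genome(bases, genes = data.frame(start = 1L, end = 900L,
                                           strand = "+"))
  cat <- do.call(rbind, lapply(seq_len(100), function(i)
    catalog_row(pos = if (i <= 85) i else 900L + (i - 85L),
                ref = "A", alt = "G")))
  res <- coding_distribution_test(cat, g)
  expect_equal(unname(res$observed), c(85L, 15L))
  expect_equal(res$statistic, (85 - 90)^2 / 90 + (15 - 10)^2 / 10)
  expect_equal(res$df, 1L)

  balanced <- do.call(rbind, lapply(seq_len(10), function(i)
    catalog_row(pos = if (i <= 9) i else 901L, ref = "A", alt = "G")))
  expect_equal(coding_distribution_test(balanced, g)$statistic, 0)

  g0 <- ma_genome(bases)
  expect_error(coding_distribution_test(cat, g0), "coding")
})

test_that("NS/S enumeration matches hand-derived codon expectations", {
  # single TTT codon: 8 of 9 single-nucleotide changes are nonsynonymous
  g <- gene_genome("TTT")
  cat <- catalog_row(pos = 3L, ref = "T", alt = "C")  # TTT->TTC synonymous
  res <- ns_s_expectation_test(cat, g)
  expect_equal(res$expected_ns_fraction, 8 / 9)
  expect_equal(unname(res$observed), c(0L, 1L))

  # eight nonsynonymous hits on TTT codons: chi-square vs 8/9 expectation
  g2 <- gene_genome(c("TTT", "TTT", "TTT"))
  cat2 <- rbind(
    do.call(rbind, lapply(c(1L, 2L, 4L, 5L, 7L, 8L), function(p)
      catalog_row(pos = p, ref = "T", alt = "C"))),  # codon pos 1/2: NS
    catalog_row(pos = 3L, ref = "T", alt = "G"),     # TTG = Leu: NS
    catalog_row(pos = 6L, ref = "T", alt = "A"))     # TTA = Leu: NS
  res2 <- ns_s_expectation_test(cat2, g2)
  expect_equal(unname(res2$observed), c(8L, 0L))
  expect_equal(res2$statistic,
               chi_square_gof(c(8, 0), 8 * c(8 / 9, 1 / 9))$statistic)
})

test_that("NS/S chi-square follows the 2-cell Pearson formula", {
  res <- chi_square_gof(c(10, 0), c(7.5, 2.5))
  expect_equal(res$statistic, (10 - 7.5)^2 / 7.5 + (0 - 2.5)^2 / 2.5)
  expect_equal(round(res$statistic, 2), 3.33)
})

test_that("NS/S enumeration agrees with an independent brute force", {
  g <- generate_reference(600, 0.5, 0.9, seed = 41)
  cat <- catalog_row(pos = g$genes$start[1], ref = g$bases[g$genes$start[1]],
                     alt = setdiff(c("A", "C", "G", "T"),
                                   g$bases[g$genes$start[1]])[1])
  mine <- ns_s_expectation_test(cat, g)$expected_ns_fraction

  # brute force with Biostrings translation over every coding change
  syn <- 0L; tot <- 0L
  for (gi in seq_len(nrow(g$genes))) {
    gene <- g$genes[gi, ]
    seqs <- paste(g$bases[gene$start:gene$end], collapse = "")
    dna <- Biostrings::DNAString(seqs)
    if (gene$strand == "-") dna <- Biostrings::reverseComplement(dna)
    s <- as.character(dna)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    for (p in seq_len(nchar(s))) {
      for (nb in setdiff(c("A", "C", "G", "T"), substr(s, p, p))) {
        mut <- s
        substr(mut, p, p) <- nb
        aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(mut)))
        tot <- tot + 1L
        if (aa2 == aa) syn <- syn + 1L
      }
    }
  }
  brute <- 1 - syn / tot
  expect_equal(mine, brute, tolerance = 1e-7)
})

test_that("bin density tiles the circular genome", {
  fake <- structure(list(length = 5190000L, terminus = 2500000L,
                         genes = data.frame()), class = "ma_genome")
  b <- bin_density(catalog_row()[0, ], fake, 50000L)
  expect_equal(b$n_bins, 104L)
  expect_true(all(b$counts == 0))
  expect_equal(b$terminus_bin, 50L)

  small <- ma_genome(rep(c("A", "C", "G", "T"), 100), terminus = 200L)
  one <- catalog_row(pos = 1L, ref = "A", alt = "G")
  b2 <- bin_density(one, small, 100L)
  expect_equal(b2$counts, c(1L, 0L, 0L, 0L))

  # invariant to catalog ordering
  cat3 <- rbind(catalog_row(pos = 350L, ref = "A", alt = "G"),
                catalog_row(pos = 10L, ref = "A", alt = "G"),
                catalog_row(pos = 150L, ref = "A", alt = "G"))
  expect_equal(bin_density(cat3, small, 100L)$counts,
               bin_density(cat3[3:1, ], small, 100L)$counts)
})

test_that("terminus t-test matches the one-sample t formula and oracle", {
  bins <- list(counts = c(1L, 1L, 1L, 9L), terminus_bin = 4L,
               bin_size = 100L, n_bins = 4L)
  res <- terminus_test(bins)
  expect_equal(res$statistic, (9 - 3) / (4 / 2))  # mean 3, sd 4, K 4
  expect_equal(res$df, 3L)
  oracle <- t.test(c(1, 1, 1, 9), mu = 9)
  expect_equal(res$statistic, -unname(oracle$statistic))
  expect_equal(res$p_value, oracle$p.value)

  flat <- list(counts = rep(5L, 104), terminus_bin = 50L)
  expect_error(terminus_test(flat), "variance")

  at_mean <- list(counts = c(1L, 3L, 2L, 2L), terminus_bin = 3L)
  expect_equal(terminus_test(at_mean)$statistic, 0)

  # excluding the terminus leaves {1,1,1}: zero reference variance
  expect_error(terminus_test(bins, exclude_terminus = TRUE), "variance")
  bins2 <- list(counts = c(1L, 2L, 3L, 9L), terminus_bin = 4L)
  excl <- terminus_test(bins2, exclude_terminus = TRUE)
  expect_equal(excl$statistic, (9 - 2) / (1 / sqrt(3)))
  expect_equal(excl$df, 2L)
})
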