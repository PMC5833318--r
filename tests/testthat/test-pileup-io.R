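test_that("pileup reader parses the 8-count dialect and flags bad rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\tA\ta\tC\tc\tG\tg\tT\tt",
               "17\t10\t12\t0\t0\t0\t0\t0\t1"), tf)
  p <- read_pileup(tf)
  expect_equal(p$pos, 17L)
  expect_equal(sum(p[, -1]), 23L)

  writeLines("pos\tA\ta\tC\tc\tG\tg\tT\tt", tf)
  expect_equal(nrow(read_pileup(tf)), 0L)

  writeLines(c("pos\tA\ta\tC\tc\tG\tg\tT\tt", "1\t2\t3\t4\t5\t6\t7"), tf)
  expect_error(read_pileup(tf), "line 2")

  writeLines(c("pos\tA\ta\tC\tc\tG\tg\tT\tt",
               "1\t2\t3\t4\t5\t6\t7\t8\t-1"), tf)
  expect_error(read_pileup(tf), "negative")
})

test_that("pileup, evidence and catalog tables round-trip exactly", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(rpois(80, 20), 10, 8,
              dimnames = list(NULL, c("A", "a", "C", "c", "G", "g",
                                      "T", "t")))
  storage.mode(m) <- "integer"
  write_pileup(m, tf)
  back <- read_pileup(tf)
  expect_equal(pileup_matrix(back, 10L), m, ignore_attr = TRUE)

  ev <- rbind(one_evidence(), one_evidence(pos = 7L, type = "insertion",
                                           size = 3L, motif = "GGA"))
  write_indel_evidence(ev, tf)
  expect_equal(read_indel_evidence(tf), ev)

  cat <- rbind(catalog_row(), catalog_row(line = 2L, pos = 50L,
                                          type = "deletion", ref = "",
                                          alt = "", size = 2L,
                                          motif = "AC"))
  write_catalog(cat, tf)
  expect_equal(read_catalog(tf), cat)
})

test_that("genome FASTA and GFF3 round-trip", {
  g <- generate_reference(600, 0.5, 0.5, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fasta(g, fa)
  write_genes_gff3(g, gff)
  g2 <- read_genome_fasta(fa, genes = gff)
  expect_identical(g2$bases, g$bases)
  expect_equal(g2$genes$start, g$genes$start)
  expect_equal(g2$genes$end, g$genes$end)
  expect_equal(g2$genes$strand, g$genes$strand)
})

test_that("VCF export is 4.2 with left-anchored indels", {
  bases <- rep(c("A", "C", "G", "T"), length.out = 300)
  bases[100] <- "A"; bases[101] <- "A"; bases[102] <- "C"
  g <- ma_genome(bases, name = "chrT")
  cat <- rbind(
    catalog_row(line = 1L, pos = 100L, type = "BPS", ref = "A",
                alt = "T"),
    # deletion of "AC" whose first removed base is 101 -> anchored at 100
    catalog_row(line = 2L, pos = 101L, type = "deletion", ref = "",
                alt = "", size = 2L, motif = "AC"),
    catalog_row(line = 1L, pos = 150L, type = "insertion", ref = "",
                alt = "", size = 3L, motif = "TTT"))
  vf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cat, g, vf)
  txt <- readLines(vf)
  expect_equal(txt[1], "##fileformat=VCFv4.2")
  recs <- read.table(text = txt[!startsWith(txt, "#")], sep = "\t",
                     stringsAsFactors = FALSE)
  del <- recs[recs$V2 == 100 & nchar(recs$V4) == 3, ]
  expect_equal(del$V4, "AAC")
  expect_equal(del$V5, "A")
  snv <- recs[recs$V2 == 100 & nchar(recs$V4) == 1, ]
  expect_equal(snv$V4, "A"); expect_equal(snv$V5, "T")

  # independent VCF parser agrees on the records
  vcf <- VariantAnnotation::readVcf(vf)
  expect_equal(length(vcf), 3L)
  expect_setequal(BiocGenerics::start(vcf), c(100L, 100L, 150L))

  write_vcf(cat[0, ], g, vf)
  expect_true(all(startsWith(readLines(vf), "#")))
  expect_error(write_vcf(catalog_row(pos = 400L), g, vf), "outside")
})
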