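#' Read a per-site read-count pileup
#'
#' The pileup dialect is a tab-separated table with header
#' `pos A a C c G g T t`: one row per covered genomic position, uppercase
#' columns counting forward-strand reads and lowercase reverse-strand
#' reads for each base. Missing positions are permitted and mean zero
#' coverage.
#'
#' @param path path to a pileup TSV.
#' @return data.frame with integer columns `pos`, `A`, `a`, `C`, `c`,
#'   `G`, `g`, `T`, `t`, sorted by position.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(integer(), 0L, 9L))
    names(out) <- c("pos", PILEUP_COLS)
    return(out)
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("pos", PILEUP_COLS))) {
    stop(sprintf("%s: line 1: expected header 'pos %s'", path,
                 paste(PILEUP_COLS, collapse = " ")))
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    out <- as.data.frame(matrix(integer(), 0L, 9L))
    names(out) <- c("pos", PILEUP_COLS)
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("%s: line %d: expected 9 columns, found %d",
                 path, bad + 1L, nf[bad]))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(fields))), ncol = 9L,
              byrow = TRUE)
  if (anyNA(m) || any(m < 0L)) {
    bad <- which(apply(m, 1L, function(r) anyNA(r) || any(r < 0L)))[1L]
    stop(sprintf("%s: line %d: non-integer or negative count",
                 path, bad + 1L))
  }
  out <- as.data.frame(m)
  names(out) <- c("pos", PILEUP_COLS)
  out[order(out$pos), , drop = FALSE]
}

#' Write a pileup count matrix
#'
#' @param counts either an L x 8 matrix (rows = positions 1..L, columns
#'   `A a C c G g T t`) or a data.frame already carrying a `pos` column.
#' @param path output path.
#' @export
write_pileup <- function(counts, path) {
  if (is.matrix(counts)) {
    counts <- data.frame(pos = seq_len(nrow(counts)), counts)
    names(counts) <- c("pos", PILEUP_COLS)
  }
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Convert a sparse pileup data.frame to a dense L x 8 count matrix
#'
#' @param pileup data.frame from [read_pileup()].
#' @param genome_length total number of sites.
#' @return integer matrix, absent positions filled with zeros.
#' @export
pileup_matrix <- function(pileup, genome_length) {
  m <- matrix(0L, genome_length, 8L, dimnames = list(NULL, PILEUP_COLS))
  if (nrow(pileup)) {
    m[pileup$pos, ] <- as.matrix(pileup[, PILEUP_COLS])
  }
  m
}

EVIDENCE_COLS <- c("pos", "type", "size", "motif", "fwd_support",
                   "rev_support", "spanning_reads", "source")

#' Read / write indel-evidence tables
#'
#' Evidence rows describe one putative indel seen by one source
#' (`aligner` or `paired-evidence`): position, type, size, motif (empty
#' for long deletions), forward/reverse supporting reads and total
#' spanning reads.
#'
#' @param path file path.
#' @return data.frame with the evidence columns.
#' @export
read_indel_evidence <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "integer",
                                         "character", "integer", "integer",
                                         "integer", "character"),
                          na.strings = NULL, stringsAsFactors = FALSE)
  if (!identical(names(ev), EVIDENCE_COLS)) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(EVIDENCE_COLS, collapse = " ")))
  }
  if (any(ev$size < 1L)) stop(sprintf("%s: indel size < 1", path))
  if (any(ev$fwd_support + ev$rev_support > ev$spanning_reads)) {
    stop(sprintf("%s: supporting reads exceed spanning reads", path))
  }
  ev
}

#' @rdname read_indel_evidence
#' @param evidence evidence data.frame.
#' @export
write_indel_evidence <- function(evidence, path) {
  evidence <- evidence[, EVIDENCE_COLS]
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

CATALOG_COLS <- c("line", "pos", "type", "ref", "alt", "size", "motif")

#' Read / write mutation catalogs
#'
#' A catalog holds one row per accepted mutation: `line`, `pos`, `type`
#' (`BPS`/`insertion`/`deletion`), `ref`/`alt` bases (empty for indels),
#' `size` in bp and `motif` (inserted or deleted sequence; may be empty
#' for very long deletions).
#'
#' @param path file path.
#' @return data.frame with the catalog columns.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "integer", "character",
                                          "character", "character",
                                          "integer", "character"),
                           na.strings = NULL, stringsAsFactors = FALSE)
  if (!identical(names(cat), CATALOG_COLS)) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(CATALOG_COLS, collapse = " ")))
  }
  cat
}

#' @rdname read_catalog
#' @param catalog catalog data.frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog[, CATALOG_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Write a genome to FASTA / read one back
#'
#' @param genome an [ma_genome].
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  s <- Biostrings::DNAStringSet(paste(genome$bases, collapse = ""))
  names(s) <- genome$name
  Biostrings::writeXStringSet(s, path)
}

#' @rdname write_genome_fasta
#' @param genes optional gene table or GFF3 path to attach.
#' @param terminus optional terminus coordinate.
#' @export
read_genome_fasta <- function(path, genes = NULL, terminus = NA) {
  s <- Biostrings::readDNAStringSet(path)
  if (is.character(genes) && length(genes) == 1L) {
    genes <- read_genes_gff3(genes)
  }
  ma_genome(as.character(s[[1L]]), genes = genes,
            name = sub("\\s.*$", "", names(s)[1L]), terminus = terminus)
}

#' Write / read gene annotation as GFF3
#'
#' Genes are exported as `gene` features; reading keeps `gene` (or CDS)
#' features and returns the interval table used by [ma_genome].
#'
#' @param genome an [ma_genome].
#' @param path file path.
#' @export
write_genes_gff3 <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome$name, nrow(g)),
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand, type = rep("gene", nrow(g)),
    ID = sprintf("gene%04d", seq_len(nrow(g))))
  rtracklayer::export(gr, path, format = "gff3")
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "CDS")]
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Export a mutation catalog as VCF 4.2
#'
#' BPS calls become SNV records. Indels are left-anchored on the base
#' before the event, per VCF convention: a deletion whose first removed
#' base is `pos` becomes `POS = pos - 1`, `REF = anchor + motif`,
#' `ALT = anchor`; an insertion after `pos` becomes `POS = pos`,
#' `REF = anchor`, `ALT = anchor + motif`. Lines are emitted as haploid
#' sample columns (GT 1 = carries the event).
#'
#' @param catalog mutation catalog.
#' @param genome an [ma_genome]; provides REF bases and the contig header.
#' @param path output path.
#' @param line_ids sample names; defaults to `line<k>` over observed ids.
#' @export
write_vcf <- function(catalog, genome, path, line_ids = NULL) {
  if (nrow(catalog) && (any(catalog$pos < 1L) ||
                        any(catalog$pos > genome$length))) {
    stop("catalog position outside genome")
  }
  if (is.null(line_ids)) {
    line_ids <- sort(unique(catalog$line))
    if (length(line_ids) == 0L) line_ids <- 1L
  }
  samples <- sprintf("line%s", line_ids)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", genome$name, genome$length),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(0)
  if (nrow(catalog)) {
    key <- with(catalog, paste(pos, type, size, ifelse(type == "BPS", alt,
                                                       motif)))
    for (k in unique(key)) {
      ev <- catalog[key == k, , drop = FALSE]
      e <- ev[1L, ]
      if (e$type == "BPS") {
        vpos <- e$pos; ref <- genome$bases[e$pos]; alt <- e$alt
      } else if (e$type == "deletion") {
        if (e$pos < 2L) stop("cannot left-anchor a deletion at position 1")
        vpos <- e$pos - 1L
        anchor <- genome$bases[vpos]
        motif <- if (nzchar(e$motif)) e$motif else
          paste(genome$bases[e$pos:(e$pos + e$size - 1L)], collapse = "")
        ref <- paste0(anchor, motif); alt <- anchor
      } else {
        vpos <- e$pos
        anchor <- genome$bases[vpos]
        ref <- anchor; alt <- paste0(anchor, e$motif)
      }
      gt <- ifelse(line_ids %in% ev$line, "1", "0")
      rows <- c(rows, paste(c(genome$name, vpos, ".", ref, alt, ".", "PASS",
                              ".", "GT", gt), collapse = "\t"))
    }
    ord <- order(as.integer(vapply(strsplit(rows, "\t"), `[[`, "", 2L)))
    rows <- rows[ord]
  }
  writeLines(c(hdr, rows), path)
}
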