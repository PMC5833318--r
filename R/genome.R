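#' Circular genome with gene annotation
#'
#' A lightweight container for a circular haploid genome: the nucleotide
#' sequence, a table of gene intervals and (optionally) the coordinate of
#' the replication terminus. All coordinates are 1-based and inclusive.
#'
#' @param sequence character vector of single bases (A/C/G/T) or a single
#'   string; stored internally as a character vector of bases.
#' @param genes data.frame with columns `start`, `end`, `strand`
#'   (`"+"`/`"-"`); gene lengths must be multiples of 3 and lie within the
#'   genome. May have zero rows.
#' @param name genome name (used as the FASTA/VCF contig id).
#' @param terminus 1-based coordinate of the replication terminus, or `NA`.
#' @return An object of class `ma_genome` with elements `name`, `bases`
#'   (character vector), `length`, `genes`, `terminus`.
#' @export
ma_genome <- function(sequence, genes = NULL, name = "chr", terminus = NA) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(toupper(sequence), "")[[1]]
  } else {
    sequence <- toupper(as.character(sequence))
  }
  if (length(sequence) == 0L) stop("genome sequence must be non-empty")
  if (!all(sequence %in% c("A", "C", "G", "T"))) {
    stop("genome sequence may only contain A/C/G/T")
  }
  if (is.null(genes)) {
    genes <- data.frame(start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes)
  if (nrow(genes)) {
    stopifnot(all(c("start", "end", "strand") %in% names(genes)))
    if (any(genes$start < 1L | genes$end > length(sequence))) {
      stop("gene intervals must lie within the genome")
    }
    len <- genes$end - genes$start + 1L
    if (any(len %% 3L != 0L)) stop("gene lengths must be multiples of 3")
  }
  structure(
    list(name = name, bases = sequence, length = length(sequence),
         genes = genes, terminus = terminus),
    class = "ma_genome"
  )
}

#' @export
print.ma_genome <- function(x, ...) {
  gc <- mean(x$bases %in% c("G", "C"))
  cat(sprintf("ma_genome '%s': %d bp circular, GC %.3f, %d genes\n",
              x$name, x$length, gc, nrow(x$genes)))
  invisible(x)
}

#' Generate a random circular reference genome
#'
#' Draws an i.i.d. nucleotide sequence at a target G+C fraction and places
#' non-overlapping genes (lengths a multiple of 3, random strand) until
#' roughly `coding_fraction` of sites are covered. The terminus is placed
#' at the site opposite position 1 (length/2), mimicking a bidirectionally
#' replicating bacterial chromosome.
#'
#' @param length genome length in bp (>= 300).
#' @param gc_content target G+C fraction, in (0, 1).
#' @param coding_fraction approximate fraction of sites inside genes.
#' @param seed integer seed; identical seeds give identical genomes.
#' @param gene_length_range candidate gene lengths are drawn uniformly in
#'   this range then rounded down to a multiple of 3.
#' @return an [ma_genome].
#' @export
generate_reference <- function(length, gc_content = 0.5, coding_fraction = 0.5,
                               seed = 1L,
                               gene_length_range = c(300L, 1500L)) {
  if (length < 300) stop("length must be >= 300")
  if (!(gc_content > 0 && gc_content < 1)) {
    stop("gc_content must lie strictly between 0 and 1")
  }
  if (coding_fraction < 0 || coding_fraction > 1) {
    stop("coding_fraction must lie in [0, 1]")
  }
  with_local_seed(seed, {
    p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
           G = gc_content / 2, T = (1 - gc_content) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    genes <- place_genes(length, coding_fraction, gene_length_range)
    ma_genome(bases, genes, name = "synthetic_chr",
              terminus = as.integer(length %/% 2L))
  })
}

# Non-overlapping gene placement by sequential scan over shuffled slots.
place_genes <- function(glen, coding_fraction, len_range) {
  genes <- data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (coding_fraction <= 0) return(genes)
  target <- coding_fraction * glen
  covered <- 0
  cursor <- 1L
  starts <- integer(); ends <- integer(); strands <- character()
  while (covered < target && cursor < glen) {
    gap <- if (coding_fraction >= 0.95) 0L else
      sample.int(max(1L, as.integer(glen * 0.01)), 1L)
    start <- cursor + gap
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    len <- min(len, glen - start + 1L)          # clamp to remaining space
    len <- (len %/% 3L) * 3L
    if (len < 3L) break
    end <- start + len - 1L
    starts <- c(starts, start); ends <- c(ends, end)
    strands <- c(strands, sample(c("+", "-"), 1L))
    covered <- covered + len
    cursor <- end + 1L
  }
  data.frame(start = starts, end = ends, strand = strands,
             stringsAsFactors = FALSE)
}

#' Circular distance between two positions
#'
#' @param a,b 1-based positions (vectorised).
#' @param glen genome length.
#' @return the minimum of the linear and wrap-around distance.
#' @export
circular_distance <- function(a, b, glen) {
  d <- abs(a - b)
  pmin(d, glen - d)
}

#' Logical mask of coding sites
#'
#' A site inside any gene interval counts as coding once, regardless of
#' overlaps.
#' @param genome an [ma_genome].
#' @return logical vector of length `genome$length`.
#' @export
coding_mask <- function(genome) {
  mask <- logical(genome$length)
  if (nrow(genome$genes)) {
    for (i in seq_len(nrow(genome$genes))) {
      mask[genome$genes$start[i]:genome$genes$end[i]] <- TRUE
    }
  }
  mask
}

# Run expr under a fixed RNG state without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rev_comp <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[bases]))
}

comp_base <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[bases])
}
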