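FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Silent-site nucleotide diversity from a codon alignment
#'
#' Eligible sites are third codon positions that are fourfold degenerate
#' and whose first two codon positions are identical (and unambiguous)
#' across all sequences, so that any third-position base is synonymous
#' (bacterial code; translation is the standard-code table). Sites
#' containing a gap or ambiguity character are excluded. pi_S is the
#' mean, over eligible sites, of the fraction of sequence pairs that
#' differ.
#'
#' @param alignment named character vector of equal-length, codon-aligned
#'   sequences, or a `Biostrings::DNAStringSet`, or a path to a FASTA
#'   file.
#' @return list with `pi_s`, `n_sites` (eligible silent sites),
#'   `n_sequences`.
#' @export
silent_site_pi <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- Biostrings::readDNAStringSet(alignment)
  }
  if (methods::is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences")
  len <- unique(nchar(alignment))
  if (length(len) != 1L) stop("sequences must be aligned (equal lengths)")
  if (len %% 3L != 0L) stop("alignment length must be a multiple of 3")

  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  n_codons <- len %/% 3L
  p1 <- mat[, seq(1L, len, by = 3L), drop = FALSE]
  p2 <- mat[, seq(2L, len, by = 3L), drop = FALSE]
  p3 <- mat[, seq(3L, len, by = 3L), drop = FALSE]

  pre <- matrix(paste0(p1, p2), nrow = n)
  conserved <- apply(pre, 2L, function(x) length(unique(x)) == 1L)
  fourfold <- pre[1L, ] %in% FOURFOLD_PREFIXES
  clean <- apply(p3, 2L, function(x) all(x %in% BASES)) &
    apply(p1, 2L, function(x) all(x %in% BASES)) &
    apply(p2, 2L, function(x) all(x %in% BASES))
  eligible <- which(conserved & fourfold & clean)
  if (!length(eligible)) stop("no eligible fourfold-degenerate sites")

  n_pairs <- n * (n - 1L) / 2L
  site_pi <- vapply(eligible, function(j) {
    tab <- table(p3[, j])
    same <- sum(tab * (tab - 1L) / 2L)
    1 - same / n_pairs
  }, numeric(1L))
  list(pi_s = mean(site_pi), n_sites = length(eligible), n_sequences = n)
}

#' Effective population size from silent-site diversity
#'
#' For a haploid organism under neutrality, `pi_S = 2 * Ne * mu`, so
#' `Ne = pi_S / (2 * mu)`.
#'
#' @param pi_s silent-site nucleotide diversity.
#' @param mu base-substitution rate per site per generation.
#' @return estimated effective population size.
#' @export
effective_population_size <- function(pi_s, mu) {
  if (mu <= 0) stop("mu must be positive")
  if (pi_s < 0) stop("pi_s must be non-negative")
  pi_s / (2 * mu)
}
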