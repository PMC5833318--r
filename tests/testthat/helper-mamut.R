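# Shared builders for small in-code fixtures.

# an 8-count pileup row: forward/reverse per base, order A a C c G g T t
counts_row <- function(A = 0, a = 0, C = 0, c = 0, G = 0, g = 0,
                       T = 0, t = 0) {
  m <- matrix(as.integer(c(A, a, C, c, G, g, T, t)), nrow = 1)
  colnames(m) <- c("A", "a", "C", "c", "G", "g", "T", "t")
  m
}

# pileup matrix where every site carries `depth` clean reads of `base`
clean_counts <- function(bases, depth = 50L) {
  L <- length(bases)
  m <- matrix(0L, L, 8L,
              dimnames = list(NULL, c("A", "a", "C", "c", "G", "g",
                                      "T", "t")))
  idx <- match(bases, c("A", "C", "G", "T"))
  fwd <- depth %/% 2L
  m[cbind(seq_len(L), 2L * idx - 1L)] <- fwd
  m[cbind(seq_len(L), 2L * idx)] <- depth - fwd
  m
}

one_evidence <- function(pos = 100L, type = "deletion", size = 2L,
                         motif = "AC", fwd = 2L, rev = 2L,
                         spanning = 10L, source = "aligner") {
  data.frame(pos = pos, type = type, size = size, motif = motif,
             fwd_support = fwd, rev_support = rev,
             spanning_reads = spanning, source = source,
             stringsAsFactors = FALSE)
}

empty_evidence <- function() one_evidence()[0L, ]

catalog_row <- function(line = 1L, pos = 100L, type = "BPS", ref = "C",
                        alt = "T", size = 1L, motif = "") {
  data.frame(line = line, pos = pos, type = type, ref = ref, alt = alt,
             size = size, motif = motif, stringsAsFactors = FALSE)
}

# small genome with a single known gene on the + strand
gene_genome <- function(codons, pad = 300L) {
  seq_chars <- c(strsplit(paste(codons, collapse = ""), "")[[1]],
                 rep(c("A", "C", "G", "T"), length.out = pad))
  ma_genome(seq_chars,
            genes = data.frame(start = 1L,
                               end = 3L * length(codons),
                               strand = "+", stringsAsFactors = FALSE),
            terminus = length(seq_chars) %/% 2L)
}
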