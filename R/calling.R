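#' Thresholds for consensus mutation calling
#'
#' The indel criteria follow the published scheme: a consensus indel
#' needs >= 30\% of spanning reads in a line indicating the same indel
#' (size and motif), >= 2 forward and >= 2 reverse supporting reads, must
#' be seen independently by both aligners, and identical events shared
#' by > 50\% of lines are progenitor variants and removed. Large indels
#' from paired-end realignment evidence need >= 6 forward and >= 6
#' reverse reads and >= 20 supporting reads overall. The BPS consensus
#' thresholds mirror that logic: the focal consensus base needs >= 80\%
#' of the line's reads with >= 2 forward and >= 2 reverse reads in each
#' aligner, sites count as analyzed only when depth >= 10 in every line,
#' and the others-consensus requires >= 80\% of the remaining lines to
#' agree.
#'
#' @param focal_frac minimum read fraction for the focal line's consensus
#'   base.
#' @param min_fwd,min_rev minimum forward / reverse reads supporting the
#'   focal base (per aligner).
#' @param indel_frac minimum supporting-read fraction for a consensus
#'   indel.
#' @param indel_min_fwd,indel_min_rev minimum forward / reverse reads for
#'   a consensus indel.
#' @param progenitor_frac events shared by strictly more than this
#'   fraction of lines are removed.
#' @param large_min_fwd,large_min_rev,large_min_total thresholds for the
#'   paired-evidence (large-indel) route.
#' @param min_depth minimum per-aligner depth in every line for a site to
#'   count as analyzed.
#' @param others_frac minimum agreement fraction among the other lines'
#'   consensus bases.
#' @return a named list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(focal_frac = 0.8, min_fwd = 2L, min_rev = 2L,
                               indel_frac = 0.30, indel_min_fwd = 2L,
                               indel_min_rev = 2L, progenitor_frac = 0.50,
                               large_min_fwd = 6L, large_min_rev = 6L,
                               large_min_total = 20L, min_depth = 10L,
                               others_frac = 0.8) {
  stopifnot(focal_frac > 0, focal_frac <= 1, indel_frac > 0, indel_frac <= 1,
            progenitor_frac > 0, progenitor_frac < 1,
            others_frac > 0, others_frac <= 1)
  structure(as.list(environment()), class = "calling_thresholds")
}

#' Per-site consensus base from an 8-count pileup matrix
#'
#' The consensus base at a site is the most frequent base when it holds
#' at least `frac` of the site's reads; ties or insufficient majority
#' yield `NA` (ambiguous site, no call).
#'
#' @param counts L x 8 matrix with columns `A a C c G g T t`.
#' @param frac minimum majority fraction.
#' @return integer vector of base indices into `c("A","C","G","T")`, `NA`
#'   where no consensus exists.
#' @export
consensus_base <- function(counts, frac = 0.8) {
  tot <- counts[, c(1L, 3L, 5L, 7L), drop = FALSE] +
    counts[, c(2L, 4L, 6L, 8L), drop = FALSE]
  depth <- rowSums(tot)
  m <- max.col(tot, ties.method = "first")
  mv <- tot[cbind(seq_len(nrow(tot)), m)]
  tied <- rowSums(tot == mv) > 1L
  ok <- depth > 0L & !tied & mv >= frac * depth
  ifelse(ok, m, NA_integer_)
}

#' Call base-pair substitutions in one focal line
#'
#' Implements the consensus scheme: a site yields a call iff (a) the
#' focal line's consensus base differs from the consensus of the other
#' lines, (b) it is supported by at least `min_fwd` forward and `min_rev`
#' reverse reads, and (c) both aligners independently satisfy (a)-(b)
#' with the same alternate base. Sites where `others` is `NA` (no
#' cross-line consensus) or outside `analyzed` are never called.
#'
#' @param counts1,counts2 L x 8 pileup count matrices for the two
#'   aligners.
#' @param others integer vector (length L) of consensus base indices
#'   across all other lines, `NA` where ambiguous.
#' @param thresholds a [calling_thresholds].
#' @param analyzed optional logical mask of analyzed sites.
#' @return data.frame with columns `pos`, `ref`, `alt` (bases), `fwd`,
#'   `rev` (aligner-1 support), `dual_aligner` (always TRUE).
#' @export
call_bps <- function(counts1, counts2, others, thresholds = calling_thresholds(),
                     analyzed = NULL) {
  L <- nrow(counts1)
  stopifnot(nrow(counts2) == L, length(others) == L)
  if (all(is.na(others))) stop("others consensus is empty")
  if (is.null(analyzed)) analyzed <- rep(TRUE, L)
  f1 <- focal_support(counts1, thresholds)
  f2 <- focal_support(counts2, thresholds)
  hit <- analyzed & !is.na(others) &
    !is.na(f1$base) & !is.na(f2$base) & f1$base == f2$base &
    f1$base != others & f1$ok & f2$ok
  idx <- which(hit)
  data.frame(pos = idx, ref = BASES[others[idx]], alt = BASES[f1$base[idx]],
             fwd = f1$fwd[idx], rev = f1$rev[idx],
             dual_aligner = rep(TRUE, length(idx)),
             stringsAsFactors = FALSE)
}

focal_support <- function(counts, thr) {
  base <- consensus_base(counts, thr$focal_frac)
  i <- seq_len(nrow(counts))
  fwd <- ifelse(is.na(base), 0L, counts[cbind(i, 2L * base - 1L)])
  rev <- ifelse(is.na(base), 0L, counts[cbind(i, 2L * base)])
  list(base = base, fwd = fwd, rev = rev,
       ok = !is.na(base) & fwd >= thr$min_fwd & rev >= thr$min_rev)
}

#' Call consensus indels for one line from dual-aligner evidence
#'
#' An indel is accepted iff identical (position, type, size, motif)
#' evidence exists in both aligner streams and each stream shows a
#' supporting fraction >= `indel_frac` of spanning reads with at least
#' `indel_min_fwd` forward and `indel_min_rev` reverse supporting reads.
#'
#' @param ev1,ev2 indel-evidence data.frames from the two aligners.
#' @param thresholds a [calling_thresholds].
#' @return data.frame of accepted indels (`pos`, `type`, `size`, `motif`,
#'   `fwd`, `rev`, `dual_aligner`).
#' @export
call_indels_consensus <- function(ev1, ev2,
                                  thresholds = calling_thresholds()) {
  ok1 <- evidence_passes(ev1, thresholds)
  ok2 <- evidence_passes(ev2, thresholds)
  a <- ev1[ok1, , drop = FALSE]
  b <- ev2[ok2, , drop = FALSE]
  keya <- with(a, paste(pos, type, size, motif))
  keyb <- with(b, paste(pos, type, size, motif))
  a <- a[keya %in% keyb, , drop = FALSE]
  data.frame(pos = a$pos, type = a$type, size = a$size, motif = a$motif,
             fwd = a$fwd_support, rev = a$rev_support,
             dual_aligner = rep(TRUE, nrow(a)), stringsAsFactors = FALSE)
}

evidence_passes <- function(ev, thr) {
  support <- ev$fwd_support + ev$rev_support
  ev$spanning_reads > 0L &
    support >= thr$indel_frac * ev$spanning_reads &
    ev$fwd_support >= thr$indel_min_fwd &
    ev$rev_support >= thr$indel_min_rev
}

#' Call large indels from paired-end realignment evidence
#'
#' Accepts a record iff it shows at least `large_min_fwd` forward and
#' `large_min_rev` reverse supporting reads and at least
#' `large_min_total` supporting reads overall.
#'
#' @param evidence paired-evidence data.frame.
#' @param thresholds a [calling_thresholds].
#' @return data.frame of accepted indels, as in [call_indels_consensus()].
#' @export
call_indels_large <- function(evidence, thresholds = calling_thresholds()) {
  support <- evidence$fwd_support + evidence$rev_support
  keep <- evidence$fwd_support >= thresholds$large_min_fwd &
    evidence$rev_support >= thresholds$large_min_rev &
    support >= thresholds$large_min_total
  e <- evidence[keep, , drop = FALSE]
  data.frame(pos = e$pos, type = e$type, size = e$size, motif = e$motif,
             fwd = e$fwd_support, rev = e$rev_support,
             dual_aligner = rep(FALSE, nrow(e)), stringsAsFactors = FALSE)
}

#' Remove progenitor variants shared by a majority of lines
#'
#' Any identical event (same position, type, size and alternate base or
#' motif) present in strictly more than `progenitor_frac` of the lines is
#' attributed to the ancestor or to reference-assembly error and removed
#' from every line. Applied to substitutions and indels alike.
#'
#' @param catalog mutation catalog across all lines.
#' @param n_lines number of lines in the experiment.
#' @param thresholds a [calling_thresholds].
#' @return the filtered catalog.
#' @export
filter_progenitor <- function(catalog, n_lines,
                              thresholds = calling_thresholds()) {
  stopifnot(n_lines >= 2)
  if (!nrow(catalog)) return(catalog)
  key <- with(catalog, paste(pos, type, size,
                             ifelse(type == "BPS", alt, motif)))
  shared <- tapply(catalog$line, key, function(x) length(unique(x)))
  drop <- names(shared)[shared > thresholds$progenitor_frac * n_lines]
  catalog[!key %in% drop, , drop = FALSE]
}

#' Run the full caller over an in-memory simulated experiment
#'
#' Orchestrates the per-line consensus BPS caller, the dual-aligner indel
#' consensus caller and the paired-evidence large-indel caller, then
#' applies the majority (progenitor) filter. Sites with per-aligner depth
#' below `min_depth` in any line are excluded from calling and from the
#' analyzed-site count `n`.
#'
#' @param sim list of per-line data as produced by [simulate_counts()]
#'   (elements `counts1`, `counts2`, `ev1`, `ev2`, `paired`).
#' @param thresholds a [calling_thresholds].
#' @return list with `catalog` (mutation catalog data.frame),
#'   `n_analyzed` (number of analyzed sites, identical across lines
#'   because the depth mask is experiment-wide) and `line_consensus`
#'   (L x n_lines matrix of per-line consensus base indices).
#' @export
call_catalog <- function(sim, thresholds = calling_thresholds()) {
  n_lines <- length(sim)
  stopifnot(n_lines >= 2)
  L <- nrow(sim[[1L]]$counts1)

  cons <- matrix(NA_integer_, L, n_lines)
  analyzed <- rep(TRUE, L)
  for (li in seq_len(n_lines)) {
    pooled <- sim[[li]]$counts1 + sim[[li]]$counts2
    cons[, li] <- consensus_base(pooled, thresholds$focal_frac)
    analyzed <- analyzed &
      rowSums(sim[[li]]$counts1) >= thresholds$min_depth &
      rowSums(sim[[li]]$counts2) >= thresholds$min_depth
  }

  # per-base tallies of line consensus across all lines, reused per focal
  tall <- vapply(1:4, function(k) rowSums(cons == k, na.rm = TRUE),
                 numeric(L))
  calls <- vector("list", n_lines)
  for (li in seq_len(n_lines)) {
    oth <- tall
    for (k in 1:4) oth[, k] <- oth[, k] - (!is.na(cons[, li]) &
                                           cons[, li] == k)
    n_oth <- rowSums(oth)
    m <- max.col(oth, ties.method = "first")
    mv <- oth[cbind(seq_len(L), m)]
    tied <- rowSums(oth == mv) > 1L
    others <- ifelse(n_oth > 0L & !tied &
                       mv >= thresholds$others_frac * n_oth, m, NA_integer_)

    bps <- call_bps(sim[[li]]$counts1, sim[[li]]$counts2, others,
                    thresholds, analyzed)
    ind <- call_indels_consensus(sim[[li]]$ev1, sim[[li]]$ev2, thresholds)
    big <- call_indels_large(sim[[li]]$paired, thresholds)
    calls[[li]] <- rbind(
      if (nrow(bps)) data.frame(line = li, pos = bps$pos, type = "BPS",
                                ref = bps$ref, alt = bps$alt, size = 1L,
                                motif = "", stringsAsFactors = FALSE),
      if (nrow(ind)) data.frame(line = li, pos = ind$pos, type = ind$type,
                                ref = "", alt = "", size = ind$size,
                                motif = ind$motif, stringsAsFactors = FALSE),
      if (nrow(big)) data.frame(line = li, pos = big$pos, type = big$type,
                                ref = "", alt = "", size = big$size,
                                motif = big$motif, stringsAsFactors = FALSE))
  }
  calls <- calls[!vapply(calls, is.null, logical(1L))]
  catalog <- if (length(calls)) do.call(rbind, calls) else empty_catalog()
  catalog <- filter_progenitor(catalog, n_lines, thresholds)
  catalog <- catalog[order(catalog$line, catalog$pos), , drop = FALSE]
  rownames(catalog) <- NULL
  list(catalog = catalog, n_analyzed = sum(analyzed),
       line_consensus = cons)
}

empty_catalog <- function() {
  data.frame(line = integer(), pos = integer(), type = character(),
             ref = character(), alt = character(), size = integer(),
             motif = character(), stringsAsFactors = FALSE)
}
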