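BPS_CLASSES <- c("A:T->G:C", "G:C->A:T", "A:T->T:A", "A:T->C:G",
                 "G:C->T:A", "G:C->C:G")

#' Classify a base-pair substitution
#'
#' Substitutions are labelled by strand-symmetric base-pair class (six
#' classes), flagged as transition (purine<->purine or
#' pyrimidine<->pyrimidine) or transversion, and as A/T-ward when the
#' ancestral pair is G:C and the derived pair is A:T or T:A.
#'
#' @param ref,alt single bases (vectorised).
#' @return data.frame with `class`, `transition`, `at_ward`.
#' @export
classify_bps <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    stop("ref and alt must be A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  # map to the pyrimidine-start representative of the base pair
  norm_ref <- ifelse(ref %in% c("A", "G"), comp_base(ref), ref)
  norm_alt <- ifelse(ref %in% c("A", "G"), comp_base(alt), alt)
  pair <- paste0(norm_ref, norm_alt)
  cls <- c(TC = "A:T->G:C", CT = "G:C->A:T", TA = "A:T->T:A",
           TG = "A:T->C:G", CA = "G:C->T:A", CG = "G:C->C:G")[pair]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- purine[ref] == purine[alt]
  at_ward <- ref %in% c("G", "C") & alt %in% c("A", "T")
  data.frame(class = unname(cls), transition = unname(transition),
             at_ward = at_ward, stringsAsFactors = FALSE)
}

#' Summarize the mutation spectrum of a catalog
#'
#' Tallies the six strand-symmetric BPS classes, transitions /
#' transversions and A/T-ward changes; splits indels into short (1-3 bp)
#' and long (>= 4 bp) classes; and accounts nucleotide turnover:
#' nucleotides lost per generation per line = sum of deletion sizes
#' divided by the summed generations of all lines (gains analogously).
#'
#' @param catalog mutation catalog.
#' @param lines per-line metadata (needs column `T_gen`), or a single
#'   total-generations number.
#' @return list of class `spectrum_summary`; see fields in the source.
#' @export
summarize_spectrum <- function(catalog, lines) {
  if (!nrow(catalog)) stop("catalog is empty")
  total_T <- if (is.numeric(lines)) sum(lines) else sum(lines$T_gen)
  bps <- catalog[catalog$type == "BPS", , drop = FALSE]
  ind <- catalog[catalog$type != "BPS", , drop = FALSE]
  cl <- if (nrow(bps)) classify_bps(bps$ref, bps$alt) else
    data.frame(class = character(), transition = logical(),
               at_ward = logical())
  class_counts <- table(factor(cl$class, levels = BPS_CLASSES))
  transitions <- sum(cl$transition)
  transversions <- nrow(bps) - transitions
  dele <- ind[ind$type == "deletion", , drop = FALSE]
  inse <- ind[ind$type == "insertion", , drop = FALSE]
  out <- list(
    n_total = nrow(catalog), n_bps = nrow(bps), n_indel = nrow(ind),
    class_counts = as.integer(class_counts),
    classes = BPS_CLASSES,
    transitions = transitions, transversions = transversions,
    ts_tv_pooled = if (transversions > 0) transitions / transversions
                   else NA_real_,
    ts_tv_defined = transversions > 0,
    at_ward = sum(cl$at_ward),
    n_deletions = nrow(dele), n_insertions = nrow(inse),
    short_deletions = sum(dele$size <= 3L),
    long_deletions = sum(dele$size >= 4L),
    short_insertions = sum(inse$size <= 3L),
    long_insertions = sum(inse$size >= 4L),
    nt_lost_per_gen = sum(dele$size) / total_T,
    nt_gained_per_gen = sum(inse$size) / total_T)
  out$deletion_insertion_fold <-
    if (out$nt_gained_per_gen > 0) out$nt_lost_per_gen / out$nt_gained_per_gen
    else NA_real_
  structure(out, class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("%d events: %d BPS (%.1f%%), %d indels (%.1f%%)\n",
              x$n_total, x$n_bps, 100 * x$n_bps / x$n_total,
              x$n_indel, 100 * x$n_indel / x$n_total))
  cat(sprintf("transitions %d/%d (%.1f%%), A/T-ward %d (%.1f%%)\n",
              x$transitions, x$n_bps, 100 * x$transitions / x$n_bps,
              x$at_ward, 100 * x$at_ward / x$n_bps))
  cat(sprintf("deletions %d/%d indels; nt lost/gen %.3g (%.1f-fold vs gain)\n",
              x$n_deletions, x$n_indel, x$nt_lost_per_gen,
              x$deletion_insertion_fold))
  invisible(x)
}

#' Conditional per-class BPS rates normalized to source-pair content
#'
#' Each class rate is its count divided by the number of genomic sites of
#' the ancestral base pair (A+T sites for A:T-sourced classes, G+C sites
#' for G:C-sourced) and by the summed generations across lines.
#'
#' @param summary a `spectrum_summary`.
#' @param genome an [ma_genome] supplying the base composition.
#' @param lines per-line metadata (column `T_gen`) or total generations.
#' @return named numeric vector of per-site per-generation class rates.
#' @export
conditional_rates <- function(summary, genome, lines) {
  total_T <- if (is.numeric(lines)) sum(lines) else sum(lines$T_gen)
  at_sites <- sum(genome$bases %in% c("A", "T"))
  gc_sites <- sum(genome$bases %in% c("G", "C"))
  if (at_sites == 0L || gc_sites == 0L) {
    stop("genome must contain both A:T and G:C sites")
  }
  denom <- ifelse(startsWith(BPS_CLASSES, "A:T"), at_sites, gc_sites)
  stats::setNames(summary$class_counts / (denom * total_T), BPS_CLASSES)
}

#' Pearson chi-square goodness-of-fit test
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` without continuity
#' correction, df = k - 1, p-value from the chi-square distribution.
#'
#' @param observed observed counts.
#' @param expected expected counts (same length, all > 0); defaults to
#'   equal allocation of the observed total.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_gof <- function(observed,
                           expected = rep(sum(observed), length(observed)) /
                             length(observed)) {
  if (length(observed) != length(expected) || length(observed) < 2L) {
    stop("observed and expected must have equal length >= 2")
  }
  if (any(expected <= 0)) stop("expected counts must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' Per-line transition/transversion ratios
#'
#' @param catalog mutation catalog.
#' @param n_lines number of lines.
#' @return data.frame with per-line `ts`, `tv` and `ts_tv` (NA where a
#'   line has no transversions; the across-line mean is taken over lines
#'   with a defined ratio).
#' @export
ts_tv_by_line <- function(catalog, n_lines) {
  bps <- catalog[catalog$type == "BPS", , drop = FALSE]
  cl <- if (nrow(bps)) classify_bps(bps$ref, bps$alt)$transition else
    logical(0)
  ts <- vapply(seq_len(n_lines), function(li)
    sum(cl[bps$line == li]), 0L)
  tv <- vapply(seq_len(n_lines), function(li)
    sum(!cl[bps$line == li]), 0L)
  data.frame(line = seq_len(n_lines), ts = ts, tv = tv,
             ts_tv = ifelse(tv > 0, ts / tv, NA_real_))
}
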