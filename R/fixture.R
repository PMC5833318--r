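# Largest-remainder allocation of an integer total across weights.
lr_alloc <- function(total, weights) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Proportionally interleave labelled items so every prefix of the output
# carries each label at close to its overall frequency (deterministic).
proportional_interleave <- function(values, labels) {
  keys <- numeric(length(labels))
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    keys[idx] <- (seq_along(idx) - 0.5) / length(idx)
  }
  values[order(keys)]
}

#' Build the printed-counts reference catalog
#'
#' Constructs a mutation catalog whose marginal totals transcribe the
#' published experiment exactly: 779 BPSs (558 transitions, 533 A/T-ward)
#' and 106 indels (73 deletions of which 47 short, 33 insertions of which
#' 25 short, one 12,581-bp deletion in a single line) over 47 lines of
#' 3,025 generations each, with 37 clustered events (21 BPSs and 16
#' indels, one triple, pairs elsewhere) closer than 50 nt. Splits the
#' publication does not print are filled deterministically: the six BPS
#' classes by largest-remainder allocation that equalises the A/T-ward
#' fraction across transitions and transversions; per-line counts by
#' even largest-remainder split; indel sizes by a 1/2/3 cycle for short
#' events and a base-4-plus-largest-remainder ladder for long ones,
#' constrained to the printed nucleotide-turnover totals.
#'
#' @param config path to a YAML marginals file (defaults to the one
#'   shipped with the package) or an equivalent list.
#' @return list with `catalog` (mutation catalog data.frame), `meta`
#'   (per-line metadata with `T_gen` and event counts), `genome_size`,
#'   `terminus`, `window` and `n_lines`.
#' @export
build_paper_fixture <- function(config = fixture_config_path()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  bps <- cfg$bps; ind <- cfg$indels; clu <- cfg$clusters
  nl <- cfg$n_lines
  glen <- cfg$genome_size

  if (bps$transitions > bps$total || bps$at_ward > bps$total) {
    stop("inconsistent marginals: class counts exceed total BPS")
  }
  if (ind$deletions + ind$insertions != ind$total ||
      ind$short_deletions > ind$deletions ||
      ind$short_insertions > ind$insertions) {
    stop("inconsistent marginals: indel splits")
  }

  class_counts <- fixture_bps_classes(bps$total, bps$transitions,
                                      bps$at_ward)
  nb <- rev(lr_alloc(bps$total, rep(1, nl)))       # per-line BPS counts
  ni <- rev(lr_alloc(ind$total, rep(1, nl)))       # per-line indel counts
  # rev(): extras go to the highest-numbered lines so low-numbered lines
  # (which host the planted clusters) keep the base allocation

  bps_events <- fixture_bps_events(class_counts, nb, nl, glen, clu)
  ind_events <- fixture_indel_events(ind, ni, nl, glen, clu)

  catalog <- rbind(bps_events, ind_events)
  catalog <- catalog[order(catalog$line, catalog$pos), ]
  rownames(catalog) <- NULL
  if (anyDuplicated(catalog[c("line", "pos")])) {
    stop("internal error: duplicate (line, pos) in fixture")
  }
  meta <- data.frame(line = seq_len(nl),
                     T_gen = rep(cfg$generations_per_line, nl),
                     n = rep(glen, nl),
                     m_bps = nb, m_indel = ni)
  list(catalog = catalog, meta = meta, genome_size = glen,
       terminus = cfg$terminus_position, window = clu$window,
       n_lines = nl)
}

#' @rdname build_paper_fixture
#' @export
fixture_config_path <- function() {
  system.file("extdata", "ma_fixture.yaml", package = "mamut",
              mustWork = TRUE)
}

# Six-class split: equalise the A/T-ward fraction across transitions and
# transversions (largest remainder), then split the non-A/T-ward
# transversions evenly.
fixture_bps_classes <- function(total, transitions, at_ward) {
  tv <- total - transitions
  shares <- lr_alloc(at_ward, c(transitions, tv))
  gcat <- shares[1L]; gcta <- shares[2L]
  if (gcta > tv || gcat > transitions) stop("inconsistent marginals")
  atgc <- transitions - gcat
  rest <- lr_alloc(tv - gcta, c(1, 1, 1))
  counts <- c(atgc, gcat, rest[1L], rest[2L], gcta, rest[3L])
  names(counts) <- BPS_CLASSES
  stopifnot(sum(counts) == total)
  counts
}

CLASS_REPS <- list(
  "A:T->G:C" = rbind(c("A", "G"), c("T", "C")),
  "G:C->A:T" = rbind(c("G", "A"), c("C", "T")),
  "A:T->T:A" = rbind(c("A", "T"), c("T", "A")),
  "A:T->C:G" = rbind(c("A", "C"), c("T", "G")),
  "G:C->T:A" = rbind(c("G", "T"), c("C", "A")),
  "G:C->C:G" = rbind(c("G", "C"), c("C", "G")))

# line-local deterministic position slots; BPS and indel slots are
# >= 100 kb apart inside a line so only planted clusters fall < 50 nt
fixture_slots <- function(line, k, indel = FALSE) {
  4000L * line + (if (indel) 100000L else 0L) +
    (seq_len(k) - 1L) * 200000L + 1L
}

fixture_bps_events <- function(class_counts, nb, nl, glen, clu) {
  labels <- rep(names(class_counts), class_counts)
  labels <- proportional_interleave(labels, labels)
  # alternate the two strand representatives within each class
  rep_idx <- integer(length(labels))
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    rep_idx[idx] <- (seq_along(idx) - 1L) %% 2L + 1L
  }
  ref <- vapply(seq_along(labels),
                function(i) CLASS_REPS[[labels[i]]][rep_idx[i], 1L], "")
  alt <- vapply(seq_along(labels),
                function(i) CLASS_REPS[[labels[i]]][rep_idx[i], 2L], "")

  line <- rep(seq_len(nl), nb)
  pos <- unlist(lapply(seq_len(nl), function(li)
    fixture_slots(li, nb[li])))

  # clusters: one triple in triple_line, pairs in lines 1, 2, 3, ...
  n_pairs <- (clu$clustered_bps - 3L) / 2L
  if (n_pairs != floor(n_pairs) || n_pairs < 0) {
    stop("clustered_bps must be 3 (triple) plus an even pair count")
  }
  tl <- clu$triple_line
  ti <- which(line == tl)[1:3]
  pos[ti] <- pos[ti[1L]] + c(0L, 20L, 40L)
  for (pl in seq_len(n_pairs)) {
    pi_ <- which(line == pl)[1:2]
    pos[pi_] <- pos[pi_[1L]] + c(0L, 30L)
  }
  data.frame(line = line, pos = pos, type = "BPS", ref = ref, alt = alt,
             size = 1L, motif = "", stringsAsFactors = FALSE)
}

# short sizes cycle 1,2,3 (trimmed from the tail if the nt total binds);
# long sizes are 4 + a largest-remainder ladder absorbing the remainder
fixture_sizes <- function(n_short, n_long, nt_total) {
  short <- rep_len(c(1L, 2L, 3L), n_short)
  extra <- nt_total - sum(short) - 4L * n_long
  i <- n_short
  while (extra < 0 && i >= 1L) {
    cut <- min(short[i] - 1L, -extra)
    short[i] <- short[i] - cut
    extra <- extra + cut
    i <- i - 1L
  }
  if (extra < 0) stop("indel nt total incompatible with size classes")
  long <- if (n_long > 0) 4L + lr_alloc(extra, seq_len(n_long)) else
    integer(0)
  list(short = short, long = long)
}

fixture_indel_events <- function(ind, ni, nl, glen, clu) {
  big <- ind$large_deletion
  del_sz <- fixture_sizes(ind$short_deletions, ind$deletions - 1L -
                            ind$short_deletions,
                          ind$deletion_nt_total - big$size)
  ins_sz <- fixture_sizes(ind$short_insertions,
                          ind$insertions - ind$short_insertions,
                          ind$insertion_nt_total)
  # two queues: short (1-3 bp) and long (>= 4 bp) events, each with
  # deletions and insertions proportionally interleaved
  mk_queue <- function(dsz, isz) {
    tp <- rep(c("deletion", "insertion"), c(length(dsz), length(isz)))
    sz <- c(dsz, isz)
    ord <- proportional_interleave(seq_along(tp), tp)
    data.frame(type = tp[ord], size = sz[ord], stringsAsFactors = FALSE)
  }
  shorts <- mk_queue(del_sz$short, ins_sz$short)
  longs <- mk_queue(del_sz$long, ins_sz$long)
  n_free <- nrow(shorts) + nrow(longs)
  long_frac <- nrow(longs) / n_free

  ni_free <- ni
  ni_free[big$line] <- ni_free[big$line] - 1L

  # cluster pair lines: reuse BPS-pair lines first, then fresh lines,
  # so that exactly lines_with_clusters distinct lines carry a cluster
  n_ipairs <- clu$clustered_indels / 2L
  n_bpairs <- (clu$clustered_bps - 3L) / 2L
  fresh <- clu$lines_with_clusters - 1L - n_bpairs   # minus triple line
  reuse <- n_ipairs - fresh
  ipair_lines <- c(seq_len(max(reuse, 0L)),
                   n_bpairs + seq_len(max(fresh, 0L)))

  rows <- vector("list", nl)
  si <- 1L; li_ <- 1L; taken_long <- 0L; taken <- 0L
  for (ln in seq_len(nl)) {
    k <- ni_free[ln]
    ev <- NULL
    reserve <- if (ln %in% ipair_lines) 2L else 0L
    if (reserve > 0L) {
      ev <- shorts[si + 0:1, , drop = FALSE]; si <- si + 2L
      taken <- taken + 2L
    }
    while (nrow2(ev) < k) {
      want_long <- li_ <= nrow(longs) &&
        taken_long < (taken + 1L) * long_frac
      if (want_long || si > nrow(shorts)) {
        ev <- rbind(ev, longs[li_, , drop = FALSE]); li_ <- li_ + 1L
        taken_long <- taken_long + 1L
      } else {
        ev <- rbind(ev, shorts[si, , drop = FALSE]); si <- si + 1L
      }
      taken <- taken + 1L
    }
    ev$line <- ln
    ev$pos <- fixture_slots(ln, k, indel = TRUE)
    if (reserve > 0L) ev$pos[2L] <- ev$pos[1L] + 20L
    rows[[ln]] <- ev
  }
  ev <- do.call(rbind, rows)
  ev <- rbind(ev, data.frame(
    type = "deletion", size = big$size, line = big$line,
    pos = fixture_slots(big$line, ni[big$line], indel = TRUE)[ni[big$line]],
    stringsAsFactors = FALSE))
  ev$ref <- ""; ev$alt <- ""
  ev$motif <- vapply(seq_len(nrow(ev)), function(i) {
    if (ev$size[i] > 1000L) "" else
      paste(rep_len(c("A", "C", "G", "T"), ev$size[i]), collapse = "")
  }, "")
  ev[, c("line", "pos", "type", "ref", "alt", "size", "motif")]
}

nrow2 <- function(x) if (is.null(x)) 0L else nrow(x)
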