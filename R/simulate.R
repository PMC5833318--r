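BASES <- c("A", "C", "G", "T")
PILEUP_COLS <- c("A", "a", "C", "c", "G", "g", "T", "t")

#' Simulation configuration for a synthetic MA experiment
#'
#' Defaults emulate the study conditions of the assay this pipeline was
#' built for: 47 haploid lines propagated for ~3,025 generations and
#' sequenced at ~100x with two independent aligners.
#'
#' @param n_lines number of MA lines.
#' @param generations generations per line (single number or per-line
#'   vector).
#' @param coverage_mean mean sequencing depth per site (Poisson).
#' @param error_rate per-base sequencing/mapping error probability.
#' @param aligner_discordance probability that an indel's evidence record
#'   is emitted by only one of the two pseudo-aligners.
#' @param n_bps,n_insertions,n_deletions total planted event counts across
#'   all lines.
#' @param n_clustered_pairs number of planted same-line event pairs closer
#'   than `cluster_window`.
#' @param cluster_window clustering window in nt.
#' @param indel_sizes candidate indel sizes (sampled uniformly).
#' @param progenitor_shared number of lines carrying one identical
#'   ancestral ("progenitor") BPS, used to exercise the >50\% filter; 0
#'   disables it.
#' @param seed integer seed controlling all randomness downstream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 47L, generations = 3025, coverage_mean = 100,
                       error_rate = 0.002, aligner_discordance = 0,
                       n_bps = 779L, n_insertions = 33L, n_deletions = 73L,
                       n_clustered_pairs = 0L, cluster_window = 50L,
                       indel_sizes = 1:6, progenitor_shared = 0L,
                       seed = 1L) {
  stopifnot(n_lines >= 1, all(generations > 0), coverage_mean > 0,
            error_rate >= 0, error_rate <= 1,
            aligner_discordance >= 0, aligner_discordance <= 1,
            n_bps >= 0, n_insertions >= 0, n_deletions >= 0,
            n_clustered_pairs >= 0, cluster_window >= 2)
  generations <- rep_len(generations, n_lines)
  structure(as.list(environment()), class = "sim_config")
}

#' Plant ground-truth mutations in a genome
#'
#' Events are drawn uniformly over eligible sites within lines chosen at
#' random (multinomial over lines), so configured totals are matched
#' exactly. Clustered pairs are planted with a same-line partner at a
#' circular distance below the cluster window. A progenitor BPS, if
#' requested, is planted identically in `progenitor_shared` lines.
#'
#' @param genome an [ma_genome].
#' @param config a [sim_config].
#' @return a `data.frame` truth catalog with columns `line`, `pos`,
#'   `type` (`BPS`/`insertion`/`deletion`), `ref`, `alt`, `size`, `motif`.
#' @export
plant_mutations <- function(genome, config) {
  n_events <- config$n_bps + config$n_insertions + config$n_deletions
  if (n_events > genome$length) {
    stop("requested event count exceeds genome size")
  }
  with_local_seed(config$seed + 104729L, {
    glen <- genome$length
    nl <- config$n_lines
    type <- c(rep("BPS", config$n_bps),
              rep("insertion", config$n_insertions),
              rep("deletion", config$n_deletions))
    line <- sample.int(nl, n_events, replace = TRUE)

    # draw unique (line, pos) pairs; keep indels off the last 20 bp so
    # deletion motifs never run past the linear sequence end
    pos <- integer(n_events)
    used <- character(0)
    for (i in seq_len(n_events)) {
      repeat {
        cand <- if (type[i] == "BPS") sample.int(glen, 1L)
                else sample.int(glen - 20L, 1L)
        key <- paste(line[i], cand)
        if (!key %in% used) break
      }
      used <- c(used, key)
      pos[i] <- cand
    }

    ref <- genome$bases[pos]
    alt <- character(n_events)
    size <- integer(n_events)
    motif <- character(n_events)
    is_bps <- type == "BPS"
    alt[is_bps] <- vapply(ref[is_bps],
                          function(b) sample(setdiff(BASES, b), 1L), "")
    size[is_bps] <- 1L
    for (i in which(!is_bps)) {
      size[i] <- sample(config$indel_sizes, 1L)
      motif[i] <- if (type[i] == "insertion") {
        paste(sample(BASES, size[i], replace = TRUE), collapse = "")
      } else {
        paste(genome$bases[pos[i]:(pos[i] + size[i] - 1L)], collapse = "")
      }
      alt[i] <- ""
      ref[i] <- ""
    }
    truth <- data.frame(line = line, pos = pos, type = type, ref = ref,
                        alt = alt, size = size, motif = motif,
                        stringsAsFactors = FALSE)

    # turn the first n_clustered_pairs BPS events into close pairs by
    # planting a partner < cluster_window away in the same line
    if (config$n_clustered_pairs > 0) {
      idx <- which(truth$type == "BPS")[seq_len(config$n_clustered_pairs)]
      if (length(idx) < config$n_clustered_pairs) {
        stop("not enough BPS events to form the requested clustered pairs")
      }
      partners <- lapply(idx, function(i) {
        off <- sample(seq_len(config$cluster_window - 1L), 1L)
        p <- ((truth$pos[i] - 1L + off) %% glen) + 1L
        b <- genome$bases[p]
        data.frame(line = truth$line[i], pos = p, type = "BPS", ref = b,
                   alt = sample(setdiff(BASES, b), 1L), size = 1L,
                   motif = "", stringsAsFactors = FALSE)
      })
      truth <- rbind(truth, do.call(rbind, partners))
    }

    if (config$progenitor_shared > 0) {
      p <- sample.int(glen, 1L)
      b <- genome$bases[p]
      a <- sample(setdiff(BASES, b), 1L)
      carriers <- sample.int(nl, config$progenitor_shared)
      truth <- rbind(truth, data.frame(
        line = carriers, pos = p, type = "BPS", ref = b, alt = a,
        size = 1L, motif = "", stringsAsFactors = FALSE))
    }
    truth <- truth[!duplicated(truth[c("line", "pos")]), ]
    truth[order(truth$line, truth$pos), ]
  })
}

#' Simulate per-line dual-aligner pileup counts and indel evidence
#'
#' For each line and each of two pseudo-aligners, per-site depths are
#' Poisson(`coverage_mean`), split 1:1 forward/reverse (binomial). Reads
#' carry the line's true base except with probability `error_rate`, where
#' a uniformly chosen other base is substituted. Planted indels produce
#' evidence records rather than altering the counts: short indels
#' (size <= 10) in both aligner evidence streams (except with probability
#' `aligner_discordance`, when one stream is dropped), long indels
#' (size > 10) as paired-end evidence records only, matching how a
#' realignment caller would see them.
#'
#' @param genome an [ma_genome].
#' @param truth truth catalog from [plant_mutations()].
#' @param config a [sim_config].
#' @return list with one element per line, each holding `counts1`/`counts2`
#'   (L x 8 integer matrices, columns `A a C c G g T t`), `ev1`/`ev2`
#'   (indel-evidence data.frames) and `paired` (paired-end evidence).
#' @export
simulate_counts <- function(genome, truth, config) {
  with_local_seed(config$seed + 15485863L, {
    lapply(seq_len(config$n_lines), function(li) {
      line_truth <- truth[truth$line == li, , drop = FALSE]
      bases <- genome$bases
      bsub <- line_truth[line_truth$type == "BPS", , drop = FALSE]
      if (nrow(bsub)) bases[bsub$pos] <- bsub$alt
      counts1 <- sample_counts_matrix(bases, config)
      counts2 <- sample_counts_matrix(bases, config)
      ind <- line_truth[line_truth$type != "BPS", , drop = FALSE]
      short <- ind[ind$size <= 10L, , drop = FALSE]
      long <- ind[ind$size > 10L, , drop = FALSE]
      ev <- make_indel_evidence(short, config)
      keep2 <- stats::runif(nrow(short)) >= config$aligner_discordance
      drop_from_1 <- !keep2 & stats::runif(nrow(short)) < 0.5
      list(counts1 = counts1, counts2 = counts2,
           ev1 = ev[keep2 | !drop_from_1, , drop = FALSE],
           ev2 = ev[keep2 | drop_from_1, , drop = FALSE],
           paired = make_indel_evidence(long, config, paired = TRUE))
    })
  })
}

sample_counts_matrix <- function(bases, config) {
  L <- length(bases)
  idx <- match(bases, BASES)
  depth <- stats::rpois(L, config$coverage_mean)
  err <- stats::rbinom(L, depth, config$error_rate)
  correct <- depth - err
  e1 <- stats::rbinom(L, err, 1 / 3)
  e2 <- stats::rbinom(L, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  cnt <- matrix(0L, L, 4L)
  cnt[cbind(seq_len(L), idx)] <- correct
  other <- matrix(0L, L, 3L)
  for (k in 1:4) {
    rows <- idx == k
    if (any(rows)) other[rows, ] <- matrix(rep((1:4)[-k], each = sum(rows)),
                                           ncol = 3L)
  }
  for (j in 1:3) {
    e <- list(e1, e2, e3)[[j]]
    ij <- cbind(seq_len(L), other[, j])
    cnt[ij] <- cnt[ij] + e
  }
  fwd <- matrix(stats::rbinom(4L * L, as.vector(cnt), 0.5), L, 4L)
  out <- matrix(0L, L, 8L, dimnames = list(NULL, PILEUP_COLS))
  out[, c(1L, 3L, 5L, 7L)] <- fwd
  out[, c(2L, 4L, 6L, 8L)] <- cnt - fwd
  out
}

make_indel_evidence <- function(ind, config, paired = FALSE) {
  n <- nrow(ind)
  spanning <- stats::rpois(n, config$coverage_mean)
  support <- stats::rbinom(n, spanning, 0.95)
  fwd <- stats::rbinom(n, support, 0.5)
  data.frame(pos = ind$pos, type = ind$type, size = ind$size,
             motif = ifelse(ind$size > 1000L, "", ind$motif),
             fwd_support = fwd, rev_support = support - fwd,
             spanning_reads = spanning,
             source = rep(if (paired) "paired-evidence" else "aligner", n),
             stringsAsFactors = FALSE)
}

#' Write simulated pileups and evidence files to disk
#'
#' Emits, per line, `line<id>.aln1.pileup.tsv` / `.aln2.pileup.tsv`
#' (columns `pos A a C c G g T t`), `line<id>.aln1.indels.tsv` /
#' `.aln2.indels.tsv` / `.paired.indels.tsv`, plus `truth.tsv`, the
#' reference FASTA and (when genes exist) a GFF3 annotation.
#'
#' @inheritParams simulate_counts
#' @param outdir output directory (created if needed).
#' @return invisibly, the in-memory simulation from [simulate_counts()].
#' @export
emit_pileups <- function(genome, truth, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(genome, truth, config)
  for (li in seq_along(sim)) {
    tag <- sprintf("line%02d", li)
    write_pileup(sim[[li]]$counts1,
                 file.path(outdir, paste0(tag, ".aln1.pileup.tsv")))
    write_pileup(sim[[li]]$counts2,
                 file.path(outdir, paste0(tag, ".aln2.pileup.tsv")))
    write_indel_evidence(sim[[li]]$ev1,
                         file.path(outdir, paste0(tag, ".aln1.indels.tsv")))
    write_indel_evidence(sim[[li]]$ev2,
                         file.path(outdir, paste0(tag, ".aln2.indels.tsv")))
    write_indel_evidence(sim[[li]]$paired,
                         file.path(outdir, paste0(tag, ".paired.indels.tsv")))
  }
  utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_genome_fasta(genome, file.path(outdir, "reference.fa"))
  if (nrow(genome$genes)) {
    write_genes_gff3(genome, file.path(outdir, "genes.gff3"))
  }
  invisible(sim)
}

#' Simulate a codon alignment of natural isolates
#'
#' Builds an ancestral coding sequence (no stop codons) and derives
#' `n_strains` sequences by mutating fourfold-degenerate third codon
#' positions: each eligible site carries a derived base in a random subset
#' of strains with per-site substitution probability `theta`. Intended as
#' a synthetic stand-in for a multi-strain silent-site alignment; only
#' silent positions vary, so all diversity is synonymous.
#'
#' @param n_strains number of sequences.
#' @param n_codons alignment length in codons.
#' @param theta probability that an eligible silent site is polymorphic.
#' @param seed integer seed.
#' @return named character vector of aligned sequences.
#' @export
simulate_strain_alignment <- function(n_strains = 8L, n_codons = 2000L,
                                      theta = 0.05, seed = 1L) {
  stopifnot(n_strains >= 2, n_codons >= 1, theta >= 0, theta <= 1)
  with_local_seed(seed + 7919L, {
    fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
    prefixes <- sample(fourfold, n_codons, replace = TRUE)
    third <- sample(BASES, n_codons, replace = TRUE)
    anc <- matrix(rep(paste0(prefixes, third), n_strains), nrow = n_strains,
                  byrow = TRUE)
    poly <- which(stats::runif(n_codons) < theta)
    for (j in poly) {
      derived <- sample(setdiff(BASES, third[j]), 1L)
      k <- sample.int(n_strains - 1L, 1L)
      who <- sample.int(n_strains, k)
      anc[who, j] <- paste0(prefixes[j], derived)
    }
    seqs <- apply(anc, 1L, paste, collapse = "")
    names(seqs) <- sprintf("strain_%02d", seq_len(n_strains))
    seqs
  })
}
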