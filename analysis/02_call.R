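#!/usr/bin/env Rscript
# Consensus-call mutations from the simulated pileups written by
# 01_simulate.R, then score the catalog against the planted truth.

library(mamut)

simdir <- "scratch/sim"
if (!file.exists(file.path(simdir, "line01.aln1.pileup.tsv"))) {
  stop("no simulated pileups found - run analysis/01_simulate.R first")
}
genome <- read_genome_fasta(file.path(simdir, "reference.fa"),
                            genes = file.path(simdir, "genes.gff3"))
truth <- read_catalog(file.path(simdir, "truth.tsv"))
n_lines <- length(list.files(simdir, pattern = "aln1\\.pileup"))

sim <- lapply(seq_len(n_lines), function(li) {
  tag <- file.path(simdir, sprintf("line%02d", li))
  list(counts1 = pileup_matrix(read_pileup(paste0(tag, ".aln1.pileup.tsv")),
                               genome$length),
       counts2 = pileup_matrix(read_pileup(paste0(tag, ".aln2.pileup.tsv")),
                               genome$length),
       ev1 = read_indel_evidence(paste0(tag, ".aln1.indels.tsv")),
       ev2 = read_indel_evidence(paste0(tag, ".aln2.indels.tsv")),
       paired = read_indel_evidence(paste0(tag, ".paired.indels.tsv")))
})

res <- call_catalog(sim, calling_thresholds())
rec <- recovery_stats(res$catalog, truth, n_lines)

write_catalog(res$catalog, "results/02_catalog.tsv")
write_vcf(res$catalog, genome, "results/02_calls.vcf")
write.table(data.frame(metric = c("recall", "precision", "n_truth",
                                  "n_called", "n_analyzed_sites"),
                       value = c(rec$recall, rec$precision, rec$n_truth,
                                 rec$n_called, res$n_analyzed)),
            "results/02_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("called %d events over %d analyzed sites\n",
            nrow(res$catalog), res$n_analyzed))
cat(sprintf("recall %.3f, precision %.3f (progenitor variant removed: %s)\n",
            rec$recall, rec$precision,
            !any(res$catalog$pos %in%
                   as.integer(names(which(table(truth$pos) > n_lines / 2))))))
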