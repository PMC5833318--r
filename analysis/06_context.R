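#!/usr/bin/env Rscript
# Genomic-context tests on the called synthetic catalog (the
# printed-counts catalog carries no sequence, so these run where a
# genome with annotation exists): coding vs noncoding distribution,
# expected NS:S ratio by codon enumeration, and terminus-bin enrichment.

library(mamut)

if (!file.exists("results/02_catalog.tsv")) {
  stop("run analysis/01_simulate.R and 02_call.R first")
}
# terminus at length/2: the convention generate_reference() uses
genome <- read_genome_fasta("scratch/sim/reference.fa",
                            genes = "scratch/sim/genes.gff3",
                            terminus = 10000L)
catalog <- read_catalog("results/02_catalog.tsv")

cd <- coding_distribution_test(catalog, genome)
ns <- ns_s_expectation_test(catalog, genome)
bins <- bin_density(catalog, genome, bin_size = 2000L)
tt_in <- terminus_test(bins)
tt_ex <- terminus_test(bins, exclude_terminus = TRUE)

cat(sprintf("coding/noncoding: %d/%d observed vs %.1f/%.1f expected; chi2 = %.3f, P = %.3f\n",
            cd$observed[1], cd$observed[2], cd$expected[1],
            cd$expected[2], cd$statistic, cd$p_value))
cat(sprintf("expected NS fraction %.3f; observed NS/S %d/%d; chi2 = %.3f, P = %.3f\n",
            ns$expected_ns_fraction, ns$observed[1], ns$observed[2],
            ns$statistic, ns$p_value))
cat(sprintf("terminus bin %d of %d: t = %.2f (df %d) incl., t = %.2f excl.\n",
            bins$terminus_bin, bins$n_bins, tt_in$statistic, tt_in$df,
            tt_ex$statistic))

tab <- data.frame(
  quantity = c("coding_chisq", "coding_p", "ns_s_chisq", "ns_s_p",
               "expected_ns_fraction", "n_bins", "terminus_t_incl",
               "terminus_t_excl"),
  value = c(cd$statistic, cd$p_value, ns$statistic, ns$p_value,
            ns$expected_ns_fraction, bins$n_bins, tt_in$statistic,
            tt_ex$statistic))
write.table(tab, "results/06_context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
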