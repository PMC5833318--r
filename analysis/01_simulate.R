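#!/usr/bin/env Rscript
# Simulate a small MA experiment with known ground truth: a 20-kb
# circular genome, 8 lines at 100x dual-aligner coverage, planted
# substitutions and indels (including one event shared by 5 of 8 lines,
# i.e. an ancestral variant the caller must reject). Pileup and evidence
# files go to scratch/sim/ (large, regenerable); the truth summary to
# results/.

library(mamut)

outdir <- "scratch/sim"
dir.create("results", showWarnings = FALSE)

genome <- generate_reference(20000, gc_content = 0.55,
                             coding_fraction = 0.6, seed = 11)
cfg <- sim_config(n_lines = 8, coverage_mean = 100, error_rate = 0.01,
                  n_bps = 40, n_insertions = 6, n_deletions = 8,
                  indel_sizes = c(1:5, 15L), n_clustered_pairs = 2,
                  progenitor_shared = 5, seed = 12)
truth <- plant_mutations(genome, cfg)
emit_pileups(genome, truth, cfg, outdir)
write_catalog(truth, "results/01_truth.tsv")

cat(sprintf("simulated %d lines over %d bp; planted %d events (%d BPS, %d indels)\n",
            cfg$n_lines, genome$length, nrow(truth),
            sum(truth$type == "BPS"), sum(truth$type != "BPS")))
cat(sprintf("one progenitor BPS shared by %d/%d lines; %d clustered pairs\n",
            cfg$progenitor_shared, cfg$n_lines, cfg$n_clustered_pairs))
cat("pileups/evidence in", outdir, "- truth in results/01_truth.tsv\n")
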