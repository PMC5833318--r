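#!/usr/bin/env Rscript
# Mutation-rate estimation: per-line and pooled BPS/indel rates with
# standard errors on the printed-counts catalog (genome-length
# denominator; the analyzed-site counts behind the published per-site
# figure are unpublished), plus generation accounting from CFU counts.

library(mamut)

fx <- build_paper_fixture()
bps <- pooled_rate(data.frame(m = fx$meta$m_bps, n = fx$meta$n,
                              T_gen = fx$meta$T_gen))
ind <- pooled_rate(data.frame(m = fx$meta$m_indel, n = fx$meta$n,
                              T_gen = fx$meta$T_gen))

tab <- data.frame(
  quantity = c("bps_rate_per_site", "bps_rate_se", "indel_rate_per_site",
               "indel_rate_se", "bps_rate_per_genome", "n_lines",
               "site_denominator"),
  value = c(bps$rate, bps$se, ind$rate, ind$se,
            per_genome_rate(bps$rate, fx$genome_size), bps$N,
            fx$genome_size))
write.table(tab, "results/04_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("BPS rate %.3g +/- %.2g per site per generation\n",
            bps$rate, bps$se))
cat(sprintf("indel rate %.3g +/- %.2g; per-genome BPS rate %.3g\n",
            ind$rate, ind$se, per_genome_rate(bps$rate, fx$genome_size)))

# generation accounting example: monthly CFU counts around 10^3 per
# colony give ~10 divisions per transfer
div <- divisions_from_cfu(c(1024, 980, 1100, 890, 1300))
gh <- generations_harmonic(div, n_transfers = 300)
cat(sprintf("harmonic mean %.2f divisions/transfer -> %.0f generations over 300 transfers\n",
            gh$harmonic_mean, gh$generations))
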