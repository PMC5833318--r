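#!/usr/bin/env Rscript
# Mutation spectrum on the printed-counts catalog: class counts,
# transition/transversion and A/T-ward fractions, indel size classes,
# deletion bias and nucleotide turnover.

library(mamut)

fx <- build_paper_fixture()
s <- summarize_spectrum(fx$catalog, fx$meta)
db <- chi_square_gof(c(s$n_deletions, s$n_insertions))
tt <- ts_tv_by_line(fx$catalog, fx$n_lines)

print(s)
cat(sprintf("deletion bias: chi2 = %.2f, df = %d, P = %.3g\n",
            db$statistic, db$df, db$p_value))
cat(sprintf("Ts/Tv pooled %.2f; per-line mean %.2f (over %d lines with >= 1 transversion)\n",
            s$ts_tv_pooled, mean(tt$ts_tv, na.rm = TRUE),
            sum(!is.na(tt$ts_tv))))

tab <- data.frame(
  quantity = c(paste0("class_", gsub("[:>-]", "", s$classes)),
               "transitions", "transversions", "at_ward",
               "short_deletions", "long_deletions", "short_insertions",
               "long_insertions", "nt_lost_per_gen", "nt_gained_per_gen",
               "deletion_insertion_fold", "deletion_bias_chisq",
               "deletion_bias_p"),
  value = c(s$class_counts, s$transitions, s$transversions, s$at_ward,
            s$short_deletions, s$long_deletions, s$short_insertions,
            s$long_insertions, s$nt_lost_per_gen, s$nt_gained_per_gen,
            s$deletion_insertion_fold, db$statistic, db$p_value))
write.table(tab, "results/05_spectrum.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
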