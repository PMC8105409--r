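#!/usr/bin/env Rscript
# Stage 3: balanced-imitation statistics on the simulated colony.
#
# Reads the stage-1 pairs table and computes the abundance-level analyses:
# similarity quartiles, detrended tutor-pupil abundance regressions per
# quartile, gain curves, the 20%-threshold diagonal bias with its
# direction-shuffle null, pooled-diversity contrasts, the per-tutor
# reversal table and the family-level CV analysis.

suppressPackageStartupMessages(library(finchsong))
pairs <- read.csv(file.path("results", "colony_pairs.csv"))

q <- quartile_partition(pairs)
reg <- do.call(rbind, lapply(levels(q), function(lv) {
  r <- abundance_regression(pairs, group = q == lv)
  data.frame(quartile = lv, slope = r$slope, residual_R2 = r$residual_R2,
             n_pairs = r$n_pairs)
}))
write.csv(reg, file.path("results", "quartile_regressions.csv"),
          row.names = FALSE)
cat("detrended abundance regressions by similarity quartile:\n")
print(reg, row.names = FALSE, digits = 3)

g <- gain_curve(pairs)
write.csv(g, file.path("results", "gain_curve.csv"), row.names = FALSE)
cat(sprintf("\ngain curve: %.2f at the lowest populated bin (centre %.2f), %.2f at the highest (centre %.2f)\n",
            g$gain[1], g$bin_center[1], g$gain[nrow(g)], g$bin_center[nrow(g)]))

bias <- direction_shuffle_test(pairs, threshold = 0.2, n_shuffles = 1000,
                               seed = 3)
cat(sprintf("diagonal bias above 20%%: observed %.3f, reverse %.3f, statistic %.3f, direct p = %.4f\n",
            bias$observed_bias, bias$reverse_bias, bias$statistic,
            bias$p_value))
write.csv(data.frame(observed_bias = bias$observed_bias,
                     reverse_bias = bias$reverse_bias,
                     statistic = bias$statistic, p_value = bias$p_value,
                     n_shuffles = bias$n_shuffles),
          file.path("results", "diagonal_bias.csv"), row.names = FALSE)

pq <- pooled_quartile_diversity(pairs, by = "tutor_diversity")
cat(sprintf("pooled song diversity: bottom quartile %.2f bits (per-bird mean %.2f), top quartile %.2f bits (mean %.2f)\n",
            pq$bottom_pooled_bits, pq$bottom_mean_bits,
            pq$top_pooled_bits, pq$top_mean_bits))

rv <- reversal_table(pairs)
write.csv(rv, file.path("results", "reversals.csv"), row.names = FALSE)
low <- rv$tutor_diversity_bits < median(rv$tutor_diversity_bits)
cat(sprintf("diversity reversals: %.0f%% of below-median tutors have more-diverse pupils on average\n",
            100 * mean(rv$direction[low] == "increase")))

fc <- family_cv_analysis(pairs)
write.csv(fc$within, file.path("results", "family_cv.csv"),
          row.names = FALSE)
cat(sprintf("similarity CV: %.2f across families vs %.2f mean within families\n",
            fc$across_cv, mean(fc$within$cv)))
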