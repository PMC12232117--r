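#!/usr/bin/env Rscript
# Stage 4: multispout pharmacology.
#
# Two-way within-subjects ANOVA (injection x sucrose concentration, both
# within mouse) on per-condition lick totals, Greenhouse-Geisser
# corrected, followed by planned paired comparisons between injections at
# each concentration.

suppressMessages(library(photobout))
coh <- read_multispout("scratch/sim/multispout.csv")
agg <- aggregate(licks ~ mouse + treatment + concentration_pct, coh, sum)
write_results(agg, "results/multispout_cell_totals.csv")

res <- rm_anova(agg, value = "licks", subject = "mouse",
                within = c("treatment", "concentration_pct"))
write_results(res, "results/multispout_anova.csv")
for (i in seq_len(nrow(res)))
  cat(sprintf("%-30s F(%.2f, %.2f) = %6.2f, p_gg = %.4g (eps = %.2f)\n",
              res$effect[i], res$df1_gg[i], res$df2_gg[i], res$F[i],
              res$p_gg[i], res$gg_epsilon[i]))

tot <- aggregate(licks ~ mouse + treatment, agg, sum)
mt <- aggregate(licks ~ treatment, tot,
                function(x) c(mean = mean(x), sem = sd(x) / sqrt(length(x))))
cat("session totals (mean +/- SEM):\n")
print(do.call(data.frame, mt), row.names = FALSE)

agg$cell <- paste0(agg$treatment, "@", agg$concentration_pct)
concs <- sort(unique(agg$concentration_pct))
pc <- planned_paired_comparisons(
  agg, value = "licks", subject = "mouse", factor_name = "cell",
  pairs = lapply(concs, function(cc)
    paste0(c("L-histidine@", "vehicle@"), cc)))
pc$concentration_pct <- concs
write_results(pc, "results/multispout_planned_comparisons.csv")
for (i in seq_len(nrow(pc)))
  cat(sprintf("  %2d%% sucrose: t(%d) = %6.2f, p = %.4g\n",
              concs[i], pc$df[i], pc$t[i], pc$p[i]))
cat("stage 4 done; tables under results/\n")
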