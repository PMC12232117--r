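#!/usr/bin/env Rscript
# Stage 3: peri-bout waveform analysis of the two-region photometry cohort.
#
# For each region: isosbestic-correct the streams, build z-scored snips
# from bouts of at least 8 s (5 s baseline, first 6 s / last 2 s of
# licking, 10 s post, 0.1-s bins), screen artifacts at the 12-unit jump
# threshold, pool snips across sessions, bootstrap the mean waveform
# (1000 resamples, 95% band), and report significant deviations from
# baseline under the six-consecutive-bin rule. Then compare the regions
# by confidence-band overlap and quantify the behavior-defined epoch AUC.

suppressMessages(library(photobout))
seed <- 20240903L
regions <- c("PVH", "VMH")
waves <- list()
aucs <- list()
for (region in regions) {
  dirs <- Sys.glob(sprintf("scratch/sim/photometry/%s_s*", region))
  if (!length(dirs)) stop("run analysis/01_simulate.R first")
  sets <- lapply(dirs, function(d) {
    b <- read_session(d)
    bouts <- detect_bouts(b$session)
    tr <- correct_isosbestic(b$recording)
    sn <- extract_snips(tr, bouts, min_bout_s = 8)
    sn <- artifact_filter(sn, threshold = 12)
    zscore_snips(sn)
  })
  pooled <- bind_snips(sets)
  cat(sprintf("%s: %d snips pooled (%d short bouts, %d edge-skipped)\n",
              region, sum(!pooled$artifact), pooled$n_skipped_short,
              pooled$n_skipped_edge))
  bw <- bootstrap_waveform(pooled, n_boot = 1000, seed = seed)
  win <- significant_windows(bw, min_consecutive = 6)
  write_results(bw, sprintf("results/waveform_%s.csv", region),
                windows = win)
  write_results(win, sprintf("results/windows_%s.csv", region))
  waves[[region]] <- bw
  aucs[[region]] <- cbind(region = region, epoch_auc(pooled))
  for (i in seq_len(nrow(win)))
    cat(sprintf("  %s window %s: %.1f to %.1f s (rel. bout start)\n",
                region, win$direction[i], win$start_s[i], win$end_s[i]))
}

cmp <- compare_waveforms(waves$PVH, waves$VMH, min_consecutive = 6)
write_results(cmp, "results/compare_PVH_VMH.csv")
for (i in seq_len(nrow(cmp)))
  cat(sprintf("regions differ (%s) from %.1f to %.1f s\n",
              ifelse(cmp$direction[i] == "a_greater", "PVH > VMH",
                     "VMH > PVH"), cmp$start_s[i], cmp$end_s[i]))

auc <- do.call(rbind, aucs)
write_results(auc, "results/epoch_auc.csv")
mean_auc <- aggregate(cbind(early_lick, late_lick, early_post, late_post)
                      ~ region, auc, mean)
cat("mean epoch AUC (z*s):\n")
print(mean_auc, row.names = FALSE)
cat("stage 3 done; waveforms, windows and AUC under results/\n")
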