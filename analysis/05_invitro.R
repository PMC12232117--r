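#!/usr/bin/env Rscript
# Stage 5: in vitro sensor specificity.
#
# Per-cell peak dF/F0 from the ROI timelapse traces (F0 = mean of the 10
# pre-ligand frames), the 2-SD outlier screen per ligand group, then a
# Welch ANOVA across ligands with Monte-Carlo Dunnett comparisons against
# the buffer control (HBSS).

suppressMessages(library(photobout))
files <- Sys.glob("scratch/sim/invitro/*_cell*.csv")
if (!length(files)) stop("run analysis/01_simulate.R first")

lig <- sub("_cell[0-9]+\\.csv$", "", basename(files))
peaks <- vapply(files, function(f)
  dff_response(read_roi_trace(f, ligand_frame = 20))$peak_dff, 1)
cells <- data.frame(ligand = lig, peak_dff = unname(peaks))
write_results(cells, "results/invitro_cell_peaks.csv")

groups <- split(cells$peak_dff, cells$ligand)
filtered <- lapply(groups, function(v) outlier_filter(v)$kept)
removed <- vapply(groups, function(v)
  length(outlier_filter(v)$removed), 1L)
cat("cells removed by the 2-SD screen, per ligand:\n")
print(removed)

ctl <- which(names(filtered) == "HBSS")
res <- welch_anova_dunnett(filtered, control_index = ctl,
                           n_mc = 100000, seed = 20240905L)
cat(sprintf("Welch ANOVA: F(%d, %.1f) = %.2f, p = %.3g\n",
            res$df1, res$df2, res$F, res$p))
cat("Dunnett vs HBSS (family-wise Monte-Carlo):\n")
print(res$dunnett, row.names = FALSE)
write_results(res$dunnett, "results/invitro_dunnett.csv")
write_results(list(F = res$F, df1 = res$df1, df2 = res$df2, p = res$p,
                   removed_per_group = as.list(removed)),
              "results/invitro_welch.json")

means <- vapply(filtered, mean, 1)
cat(sprintf("mean peak dF/F0: histamine %.2f (%.0f%% increase), ",
            means[["histamine"]], 100 * means[["histamine"]]))
cat(sprintf("acetylcholine %.2f, ratio %.1fx\n",
            means[["acetylcholine"]],
            means[["histamine"]] / means[["acetylcholine"]]))
cat("stage 5 done; tables under results/\n")
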