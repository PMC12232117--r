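#!/usr/bin/env Rscript
# Stage 1: simulate the full synthetic study.
#
# Generates (a) behavior-only lick sessions for 8 mice in each of the four
# conditions (Restricted / Light / Dark / Sucralose), (b) two-channel
# photometry bundles for a food-restricted two-region cohort
# (paraventricular-like rebound truth vs ventromedial-like sustained
# suppression), (c) a multispout crossover cohort (vehicle vs
# L-histidine-like treatment), and (d) in vitro ROI timelapse traces for a
# ligand panel. Bundles go under scratch/sim/ (regenerable), summary
# tables under results/.

suppressMessages(library(photobout))
seed <- 20240901L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)

## (a) behavior-only sessions, 8 mice x 4 conditions -----------------------
conditions <- c("Restricted", "Light", "Dark", "Sucralose")
behavior <- list()
k <- 0L
for (m in 1:8) {
  for (cond in conditions) {
    k <- k + 1L
    s <- gen_lick_session(condition_bout_model(cond), condition = cond,
                          seed = seed + 10L * m + match(cond, conditions),
                          mouse_id = sprintf("m%02d", m))
    dir <- sprintf("scratch/sim/behavior/m%02d_%s", m, cond)
    write_session(s, NULL, dir)
    behavior[[k]] <- data.frame(mouse = s$mouse_id, condition = cond,
                                n_licks = length(s$lick_times_s))
  }
}
behavior <- do.call(rbind, behavior)
cat(sprintf("behavior: %d sessions written (%d-%d licks each)\n",
            nrow(behavior), min(behavior$n_licks), max(behavior$n_licks)))

## (b) photometry bundles: 4 sessions per region ---------------------------
truths <- list(PVH = pvh_truth, VMH = vmh_truth)
for (region in names(truths)) {
  for (i in 1:4) {
    s <- gen_lick_session(condition_bout_model("Restricted"),
                          seed = seed + 100L * match(region,
                                                     names(truths)) + i,
                          mouse_id = sprintf("%s_m%02d", region, i),
                          region = region)
    rec <- gen_photometry(s, truths[[region]](seed = seed + 500L + i))
    write_session(s, rec, sprintf("scratch/sim/photometry/%s_s%02d",
                                  region, i))
  }
  cat(sprintf("photometry: 4 %s bundles written\n", region))
}

## (c) multispout cohort ----------------------------------------------------
coh <- gen_multispout_cohort(n_mice = 8, seed = seed + 900L)
write_multispout(coh, "scratch/sim/multispout.csv")
cat(sprintf("multispout: %d trials over %d mice x 2 injections\n",
            nrow(coh), length(unique(coh$mouse))))

## (d) in vitro ligand panel: 30 cells per ligand ---------------------------
# programmed plateau responses; only the true ligand drives a large one
panel <- c(histamine = 1.5, acetylcholine = 0.12, HBSS = 0,
           serotonin = 0, dopamine = 0, glutamate = 0,
           norepinephrine = 0, GABA = 0)
dir.create("scratch/sim/invitro", recursive = TRUE, showWarnings = FALSE)
for (lig in names(panel)) {
  for (cell in 1:30) {
    tr <- gen_roi_trace(peak_dff = panel[[lig]], noise_sd = 2,
                        seed = seed + 31L * match(lig, names(panel)) + cell)
    write_roi_trace(tr, sprintf("scratch/sim/invitro/%s_cell%02d.csv",
                                lig, cell))
  }
}
cat(sprintf("in vitro: %d ROI traces written for %d ligands\n",
            30 * length(panel), length(panel)))
write.csv(data.frame(ligand = names(panel), programmed_peak_dff = panel),
          "results/invitro_programmed_panel.csv", row.names = FALSE)
cat("stage 1 done; bundles under scratch/sim/\n")
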