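#' Pipeline run configuration
#'
#' Collects every analysis parameter with defaults at the study values:
#' bouts are clusters of >= 3 licks split by 10-s gaps; snips span 5 s
#' before the bout, the first 6 s and last 2 s of licking, and 10 s after,
#' in 0.1-s bins; the artifact threshold on consecutive-bin jumps is 12;
#' waveforms use 1000 bootstrap resamples, a 95% confidence band and a
#' 6-consecutive-bin significance rule.
#'
#' @param min_licks,gap_s Bout definition.
#' @param pre_s,post_s,bin_s Snip layout.
#' @param min_bout_s Minimum bout duration for snip inclusion (8 s for
#'   the region comparison; 4 s for the condition analysis).
#' @param artifact_threshold Consecutive-bin jump threshold.
#' @param n_boot,alpha,min_consecutive Waveform inference parameters.
#' @param fs_hz Sampling rate for simulated streams.
#' @param seed Master seed; stages derive their own seeds by fixed
#'   offsets.
#' @param n_sessions Simulated sessions per region.
#' @return A `run_config` list.
#' @export
run_config <- function(min_licks = 3, gap_s = 10, pre_s = 5, post_s = 10,
                       bin_s = 0.1, min_bout_s = 8,
                       artifact_threshold = 12, n_boot = 1000,
                       alpha = 0.05, min_consecutive = 6, fs_hz = 100,
                       seed = 1L, n_sessions = 3) {
  structure(as.list(environment()), class = "run_config")
}

#' Simulate, preprocess and analyze a two-region cohort
#'
#' End-to-end run over synthetic data: simulates `n_sessions`
#' food-restricted sessions per region (paraventricular-like rebound
#' truth vs ventromedial-like sustained-suppression truth), writes the
#' session bundles, detects bouts, builds corrected z-scored snips,
#' computes each region's bootstrapped waveform with significance
#' windows, compares the regions, and writes all products plus a run
#' manifest recording parameters, seeds and per-stage counts. Reruns with
#' the same config are identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The run manifest (list), invisibly; all products are written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truths <- list(PVH = pvh_truth, VMH = vmh_truth)
  counts <- list()
  waves <- list()
  for (region in names(truths)) {
    snip_sets <- list()
    n_bouts_region <- 0L
    for (s in seq_len(config$n_sessions)) {
      seed_s <- (config$seed %% 1000000L) * 1000L +
        match(region, names(truths)) * 100L + s
      model <- condition_bout_model("Restricted")
      sess <- gen_lick_session(model, condition = "Restricted",
                               seed = seed_s,
                               mouse_id = sprintf("%s_m%02d", region, s),
                               region = region)
      truth <- truths[[region]](seed = seed_s + 17L)
      rec <- gen_photometry(sess, truth, fs_hz = config$fs_hz)
      bundle <- file.path(out_dir, "bundles",
                          sprintf("%s_s%02d", region, s))
      write_session(sess, rec, bundle)
      bouts <- detect_bouts(sess, min_licks = config$min_licks,
                            gap_s = config$gap_s)
      write_results(bouts, file.path(bundle, "bouts.csv"))
      n_bouts_region <- n_bouts_region + nrow(bouts)
      trace <- correct_isosbestic(rec)
      sn <- extract_snips(trace, bouts, min_bout_s = config$min_bout_s,
                          pre_s = config$pre_s, post_s = config$post_s,
                          bin_s = config$bin_s)
      sn <- artifact_filter(sn, threshold = config$artifact_threshold)
      sn <- zscore_snips(sn)
      snip_sets[[s]] <- sn
    }
    pooled <- bind_snips(snip_sets)
    bw <- bootstrap_waveform(pooled, n_boot = config$n_boot,
                             alpha = config$alpha,
                             seed = config$seed + 7L)
    win <- significant_windows(bw,
                               min_consecutive = config$min_consecutive)
    write_results(bw, file.path(out_dir,
                                sprintf("waveform_%s.csv", region)),
                  windows = win)
    write_results(win, file.path(out_dir,
                                 sprintf("windows_%s.csv", region)))
    waves[[region]] <- bw
    counts[[region]] <- list(
      bouts_detected = n_bouts_region,
      snips_kept = sum(!pooled$artifact),
      snips_removed_artifact = sum(vapply(snip_sets, function(x)
        x$n_removed_artifact %||% 0L, 1L)),
      snips_skipped_edge = pooled$n_skipped_edge,
      snips_skipped_short = pooled$n_skipped_short,
      windows = nrow(win))
  }
  cmp <- compare_waveforms(waves$PVH, waves$VMH,
                           min_consecutive = config$min_consecutive)
  write_results(cmp, file.path(out_dir, "compare_PVH_VMH.csv"))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("photobout")),
                   parameters = unclass(config), stages = counts,
                   comparison_windows = nrow(cmp))
  write_results(manifest, file.path(out_dir, "manifest.json"))
  if (config$n_boot < 2)
    warning("n_boot < 2: confidence band is degenerate", call. = FALSE)
  invisible(manifest)
}
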