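test_that("pure common-mode input is corrected to zero", {
  t <- (0:29999) / 100
  ctrl <- 20 + 80 * exp(-t / 600) + 5 * sin(2 * pi * t / 300)
  rec <- photometry_recording(2 * ctrl + 3, ctrl, 100)
  tr <- correct_isosbestic(rec)
  expect_lt(max(abs(tr$values)), 1e-9)
  expect_equal(tr$gain, 2, tolerance = 1e-9)
})

test_that("a sensor-only transient survives correction", {
  s <- gen_lick_session(condition_bout_model("Restricted"), seed = 11)
  truth <- pvh_truth(noise_sd = 0, seed = 2)
  rec <- gen_photometry(s, truth)
  tr <- correct_isosbestic(rec)
  recov <- tr$values * tr$baseline  # back to raw signal units
  tb <- attr(s, "truth_bouts")
  t <- (seq_along(recov) - 1) / tr$fs_hz
  # depth relative to each bout's own 5-s pre-baseline
  depths <- vapply(seq_len(nrow(tb)), function(i) {
    pre <- recov[t >= tb$start_s[i] - 5 & t < tb$start_s[i]]
    during <- recov[t >= tb$start_s[i] & t <= tb$end_s[i]]
    mean(pre) - min(during)
  }, 1)
  expect_gt(median(depths) / truth$transient_amplitude, 0.9)
  expect_lt(abs(median(depths) / truth$transient_amplitude - 1), 0.1)
})

test_that("shared artifacts are rejected to the noise floor", {
  s <- gen_lick_session(bout_model(bouts_per_session = 0), seed = 2)
  truth <- ground_truth(transient_amplitude = 0, noise_sd = 0.03,
                        artifact_times_s = c(100, 900), seed = 3)
  rec <- gen_photometry(s, truth, signal_gain = 1.5)
  tr <- correct_isosbestic(rec)
  t <- (seq_along(tr$values) - 1) / tr$fs_hz
  noise_floor <- sd(tr$values[t > 200 & t < 800])
  near <- abs(t - 100) < 1 | abs(t - 900) < 1
  expect_lt(max(abs(tr$values[near])), 5 * noise_floor)
  expect_lt(mean(abs(tr$values)), 3 * noise_floor)
})

test_that("correction rejects short or degenerate inputs", {
  expect_error(correct_isosbestic(
    photometry_recording(rnorm(100), rnorm(100), 100)), "60 s")
  expect_error(correct_isosbestic(
    photometry_recording(rnorm(12000), rep(1, 12000), 100)), "constant")
})

test_that("snips use the fixed 230-bin layout with literal 6+2 windows", {
  lay <- snip_layout()
  expect_equal(lay$n_bins, 230L)
  expect_equal(lay$baseline, 1:50)
  expect_equal(lay$lick_early, 51:110)
  expect_equal(lay$lick_late, 111:130)
  expect_equal(lay$post, 131:230)
  # trace = time itself, so bin means reveal which times each bin covers
  fs <- 100
  vals <- (0:(600 * fs - 1)) / fs
  tr <- fake_trace(vals, fs)
  # 10-s bout at t=100: early bins are the literal first 6 s
  sn <- extract_snips(tr, bout_row(100, 110), min_bout_s = 8)
  expect_equal(nrow(sn$raw), 1)
  centers <- sn$raw[1, ]
  expect_equal(centers[51], 100 + 0.05, tolerance = 0.01)
  expect_equal(centers[110], 105.9 + 0.05, tolerance = 0.01)
  expect_equal(centers[111], 108 + 0.05, tolerance = 0.01)  # last 2 s
  expect_equal(centers[130], 109.9 + 0.05, tolerance = 0.01)
  expect_equal(centers[131], 110 + 0.05, tolerance = 0.01)  # post
  # 4-s bout: first 2 s time-rescaled across the 60-bin early grid
  sn4 <- extract_snips(tr, bout_row(100, 104), min_bout_s = 4)
  c4 <- sn4$raw[1, ]
  expect_equal(c4[51], 100 + 1 / 60, tolerance = 0.02)
  expect_equal(c4[110], 102 - 1 / 60, tolerance = 0.02)
  expect_equal(c4[111], 102 + 0.05, tolerance = 0.01)
})

test_that("bouts near the recording edges are skipped and counted", {
  tr <- fake_trace(rnorm(3000), 100)  # 30 s
  bouts <- rbind(bout_row(2, 12),    # pre window truncated
                 bout_row(10, 22))   # post window overruns the recording
  expect_message(sn <- extract_snips(tr, bouts, min_bout_s = 8),
                 "skipped")
  expect_equal(sn$n_skipped_edge, 2L)
  expect_equal(nrow(sn$raw), 0)
  tr2 <- fake_trace(rnorm(4000), 100)  # 40 s
  sn2 <- extract_snips(tr2, bout_row(10, 20), min_bout_s = 8)
  expect_equal(nrow(sn2$raw), 1)
})

test_that("bin_s must divide the segment lengths", {
  expect_error(snip_layout(bin_s = 0.3), "divide")
})

test_that("z-scoring normalizes each snip to its own baseline", {
  set.seed(8)
  tr <- fake_trace(rnorm(6000, 10, 2), 100)
  sn <- extract_snips(tr, bout_row(20, 30), min_bout_s = 8)
  sn <- zscore_snips(sn)
  lay <- sn$layout
  expect_equal(mean(sn$z[1, lay$baseline]), 0, tolerance = 1e-9)
  expect_equal(sd(sn$z[1, lay$baseline]), 1, tolerance = 1e-9)
  # direct arithmetic: a value at baseline mean + 2 sd has z = 2
  v <- sn$baseline_mean[1] + 2 * sn$baseline_sd[1]
  expect_equal((v - sn$baseline_mean[1]) / sn$baseline_sd[1], 2)
})

test_that("constant snips are flagged as unnormalizable", {
  tr <- fake_trace(rep(5, 6000), 100)
  sn <- extract_snips(tr, bout_row(20, 30), min_bout_s = 8)
  expect_message(sn <- zscore_snips(sn), "flagged")
  expect_true(sn$artifact[1])
})

test_that("artifact screen applies a strict threshold on bin jumps", {
  lay <- snip_layout()
  mk <- function(step) {
    sn <- extract_snips(fake_trace(rep(0, 6000), 100), bout_row(20, 30),
                        min_bout_s = 8)
    sn$raw[1, 100] <- step  # single step of `step` between adjacent bins
    sn
  }
  expect_message(out13 <- artifact_filter(mk(13)), "removed")
  expect_equal(nrow(out13$raw), 0)
  expect_equal(out13$n_removed_artifact, 1L)
  out119 <- artifact_filter(mk(11.9))
  expect_equal(nrow(out119$raw), 1)
  # all-zero snips have no jumps and are kept
  out0 <- artifact_filter(mk(0))
  expect_equal(nrow(out0$raw), 1)
  # a jump of exactly the threshold is kept (strictly greater than)
  out12 <- artifact_filter(mk(12))
  expect_equal(nrow(out12$raw), 1)
})

test_that("scaling both channels leaves z-scored snips unchanged", {
  s <- gen_lick_session(condition_bout_model("Restricted"), seed = 21)
  truth <- pvh_truth(seed = 3)
  rec <- gen_photometry(s, truth)
  rec2 <- photometry_recording(rec$ch_signal * 7.3, rec$ch_control * 7.3,
                               rec$fs_hz)
  bouts <- detect_bouts(s)
  z1 <- zscore_snips(extract_snips(correct_isosbestic(rec), bouts, 8))
  z2 <- zscore_snips(extract_snips(correct_isosbestic(rec2), bouts, 8))
  expect_equal(z1$z, z2$z, tolerance = 1e-6)
})
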