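test_that("session bundles round-trip through write and read", {
  s <- gen_lick_session(bout_model(session_duration_s = 120,
                                   bouts_per_session = 3), seed = 3,
                        mouse_id = "m7", region = "PVH")
  rec <- gen_photometry(s, ground_truth(seed = 2), fs_hz = 50)
  dir <- withr::local_tempdir()
  write_session(s, rec, dir)
  back <- read_session(dir)
  expect_equal(back$session$lick_times_s, s$lick_times_s)
  expect_equal(back$session$mouse_id, "m7")
  expect_equal(back$session$region, "PVH")
  expect_equal(back$recording$ch_signal, rec$ch_signal,
               tolerance = 1e-12)
  expect_equal(back$recording$fs_hz, 50)
})

test_that("manifest vocabulary is closed and missing files are named", {
  s <- lick_session(c(1, 2, 3), 60, region = "none")
  dir <- withr::local_tempdir()
  write_session(s, NULL, dir)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  mf$condition <- "Fasted"
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  expect_error(read_session(dir), "Restricted, Light, Dark, Sucralose")
  expect_error(read_session(file.path(dir, "nope")), "manifest.json")
})

test_that("unsorted or duplicated lick files are repaired with warnings", {
  dir <- withr::local_tempdir()
  s <- lick_session(c(1, 2, 3), 60)
  write_session(s, NULL, dir)
  write.csv(data.frame(time_s = c(2, 1, 3, 3)),
            file.path(dir, "licks.csv"), row.names = FALSE)
  expect_warning(expect_warning(back <- read_session(dir), "unsorted"),
                 "duplicate")
  expect_equal(back$session$lick_times_s, c(1, 2, 3))
})

test_that("stream length inconsistent with the manifest is a format error", {
  s <- lick_session(c(1, 2, 3), 60)
  rec <- photometry_recording(rnorm(3000), rnorm(3000), 50)  # 60 s @ 50 Hz
  dir <- withr::local_tempdir()
  write_session(s, rec, dir)
  ph <- read.csv(file.path(dir, "photometry.csv"))
  write.csv(ph[1:2000, ], file.path(dir, "photometry.csv"),
            row.names = FALSE)  # 20 s missing
  expect_error(read_session(dir), "inconsistent")
})

test_that("waveform results round-trip in long format", {
  set.seed(12)
  x <- matrix(rnorm(12 * 230), 12)
  bw <- bootstrap_waveform(x, n_boot = 200, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(bw, f)
  back <- read_waveform(f)
  expect_equal(back$mean, bw$mean, tolerance = 1e-12)
  expect_equal(back$ci_lo, bw$ci_lo, tolerance = 1e-12)
  expect_equal(back$ci_hi, bw$ci_hi, tolerance = 1e-12)
  expect_equal(back$time_s, bw$time_s, tolerance = 1e-12)
})

test_that("significance windows serialize as second pairs, even when empty", {
  lo <- rep(-1, 230); hi <- rep(1, 230)
  hi[131:140] <- -0.5
  w <- significant_windows(fake_waveform(rep(0, 230), lo, hi))
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(w, f)
  back <- read_windows(f)
  expect_equal(back$start_s, w$start_s)
  expect_equal(back$end_s, w$end_s)
  expect_equal(back$direction, w$direction)
  # empty windows still give a valid header-only file
  empty <- significant_windows(fake_waveform(rep(0, 230), lo, rep(1, 230)))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results(empty, f2)
  back2 <- read_windows(f2)
  expect_equal(nrow(back2), 0)
  expect_named(back2, c("start_s", "end_s", "direction"))
})

test_that("multispout and ROI tables round-trip", {
  ms <- gen_multispout_session("m1", seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_multispout(ms, f)
  back <- read_multispout(f)
  expect_equal(back$licks, ms$licks)
  expect_equal(back$concentration_pct, ms$concentration_pct)
  tr <- gen_roi_trace(seed = 4)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_roi_trace(tr, f2)
  back2 <- read_roi_trace(f2, ligand_frame = tr$ligand_frame)
  expect_equal(back2$frames, tr$frames, tolerance = 1e-12)
})
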