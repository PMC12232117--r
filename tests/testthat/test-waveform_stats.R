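test_that("identical snips give a degenerate band equal to the mean", {
  v <- sin(seq_len(230) / 10)
  x <- matrix(rep(v, 10), nrow = 10, byrow = TRUE)
  bw <- bootstrap_waveform(x, n_boot = 200, seed = 1)
  expect_equal(bw$mean, v)
  expect_equal(bw$ci_lo, v)
  expect_equal(bw$ci_hi, v)
})

test_that("bootstrap is deterministic given the seed and needs 2 snips", {
  set.seed(2)
  x <- matrix(rnorm(20 * 230), 20)
  b1 <- bootstrap_waveform(x, n_boot = 100, seed = 7)
  b2 <- bootstrap_waveform(x, n_boot = 100, seed = 7)
  expect_identical(b1$ci_lo, b2$ci_lo)
  b3 <- bootstrap_waveform(x, n_boot = 100, seed = 8)
  expect_false(identical(b1$ci_lo, b3$ci_lo))
  expect_error(bootstrap_waveform(x[1, , drop = FALSE]), "at least 2")
})

test_that("confidence band width shrinks like 1/sqrt(n)", {
  set.seed(5)
  w <- function(n) {
    x <- matrix(rnorm(n * 230), n)
    bw <- bootstrap_waveform(x, n_boot = 400, seed = 3)
    mean(bw$ci_hi - bw$ci_lo)
  }
  ratio <- w(50) / w(200)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("band always contains the sample mean on well-behaved data", {
  set.seed(6)
  x <- matrix(rnorm(60 * 230), 60)
  bw <- bootstrap_waveform(x, n_boot = 1000, seed = 4)
  frac <- mean(bw$ci_lo <= bw$mean & bw$mean <= bw$ci_hi)
  expect_gte(frac, 0.99)
})

test_that("windows honour the consecutive-bin rule", {
  lo <- rep(-1, 230); hi <- rep(1, 230)
  # band below zero on bins 131..140 (10 bins)
  lo10 <- lo; hi10 <- hi
  lo10[131:140] <- -3; hi10[131:140] <- -0.5
  w <- significant_windows(fake_waveform(rep(0, 230), lo10, hi10))
  expect_equal(nrow(w), 1)
  expect_equal(w$direction, "below")
  expect_equal(w$start_bin, 131)
  expect_equal(w$end_bin, 140)
  # exactly 5 consecutive bins is not enough
  lo5 <- lo; hi5 <- hi
  hi5[131:135] <- -0.5
  expect_equal(nrow(significant_windows(
    fake_waveform(rep(0, 230), lo5, hi5))), 0)
  # 6 bins qualifies
  hi6 <- hi; hi6[131:136] <- -0.5
  expect_equal(nrow(significant_windows(
    fake_waveform(rep(0, 230), lo, hi6))), 1)
})

test_that("raising min_consecutive never adds windows", {
  set.seed(9)
  for (rep in 1:20) {
    hit <- rnorm(230, sd = 0.5)
    bw <- fake_waveform(hit, hit - 0.3, hit + 0.3)
    n_win <- vapply(1:10, function(m)
      nrow(significant_windows(bw, min_consecutive = m)), 1L)
    expect_true(all(diff(n_win) <= 0))
  }
})

test_that("baseline bins are excluded from reporting by default", {
  lo <- rep(0.5, 230); hi <- rep(1, 230)  # everywhere above zero
  bw <- fake_waveform(rep(0.75, 230), lo, hi)
  w <- significant_windows(bw)
  expect_equal(w$start_bin, 51)
  w_all <- significant_windows(bw, exclude_baseline = FALSE)
  expect_equal(w_all$start_bin, 1)
})

test_that("waveform comparison flags disjoint bands only", {
  m <- rep(0, 230)
  a <- fake_waveform(m + 1, m + 0.5, m + 1.5)
  b <- fake_waveform(m - 1, m - 1.5, m - 0.5)
  w <- compare_waveforms(a, b)
  expect_equal(nrow(w), 1)
  expect_equal(w$direction, "a_greater")
  expect_equal(w$start_bin, 51)  # baseline excluded
  # identity: no windows
  expect_equal(nrow(compare_waveforms(a, a)), 0)
  # symmetry up to direction labels
  w_rev <- compare_waveforms(b, a)
  expect_equal(w_rev$start_bin, w$start_bin)
  expect_equal(w_rev$direction, "b_greater")
  # touching at exactly one endpoint counts as overlapping
  c_ <- fake_waveform(m, m - 0.5, m + 0.5)
  d_ <- fake_waveform(m + 1, m + 0.5, m + 1.5)
  expect_equal(nrow(compare_waveforms(c_, d_)), 0)
  # grid mismatch is an error
  short <- fake_waveform(rep(0, 10), rep(-1, 10), rep(1, 10),
                         layout = snip_layout(pre_s = 0.5, early_s = 0.2,
                                              late_s = 0.1, post_s = 0.2))
  expect_error(compare_waveforms(a, short), "grid")
})

test_that("epoch AUC is the signed bin sum in z seconds", {
  lay <- snip_layout()
  z <- rep(0, 230)
  expect_equal(unlist(epoch_auc(z)), c(early_lick = 0, late_lick = 0,
                                       early_post = 0, late_post = 0))
  z1 <- rep(0, 230)
  z1[lay$post[1:50]] <- 1       # z == 1 across the 5-s early post epoch
  expect_equal(epoch_auc(z1)$early_post, 5)
  expect_equal(epoch_auc(z1)$late_post, 0)
  z2 <- rep(0, 230)
  z2[lay$lick_late] <- -2       # -2 z over the 2-s late lick epoch
  expect_equal(epoch_auc(z2)$late_lick, -4)
})

test_that("mouse-stratified resampling preserves determinism", {
  set.seed(11)
  x <- matrix(rnorm(30 * 230), 30)
  strat <- rep(c("a", "b", "c"), each = 10)
  b1 <- bootstrap_waveform(x, n_boot = 100, seed = 5, stratify_by = strat)
  b2 <- bootstrap_waveform(x, n_boot = 100, seed = 5, stratify_by = strat)
  expect_identical(b1$ci_hi, b2$ci_hi)
  expect_equal(b1$mean, colMeans(x))
})
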