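# Independent oracle for bout detection: enumerate every contiguous lick
# segment and keep those that are valid maximal clusters (all internal
# inter-lick intervals < gap, and separated from the neighboring licks by
# >= gap on both sides). O(n^2), independent of the run-length
# implementation under test.
oracle_bouts <- function(t, min_licks = 3, gap = 10) {
  n <- length(t)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    n_licks = integer(0))
  if (!n) return(out)
  for (i in seq_len(n)) {
    for (j in i:n) {
      internal_ok <- j == i || all(diff(t[i:j]) < gap)
      before_ok <- i == 1 || (t[i] - t[i - 1]) >= gap
      after_ok <- j == n || (t[j + 1] - t[j]) >= gap
      if (internal_ok && before_ok && after_ok && (j - i + 1) >= min_licks)
        out <- rbind(out, data.frame(start_s = t[i], end_s = t[j],
                                     n_licks = j - i + 1L))
    }
  }
  out[order(out$start_s), , drop = FALSE]
}

# Random lick train with a mixture of short intra-bout intervals and long
# inter-bout gaps (straddling the 10-s rule).
random_lick_train <- function(n) {
  if (n == 0) return(numeric(0))
  ili <- ifelse(stats::runif(n - 1) < 0.7,
                stats::runif(n - 1, 0.05, 0.5),
                stats::runif(n - 1, 8, 15))
  cumsum(c(stats::runif(1, 0, 5), ili))
}

# Fabricate a corrected trace directly (unit-variance baseline of ones).
fake_trace <- function(values, fs_hz = 100, t0_s = 0) {
  structure(list(values = values, fs_hz = fs_hz, t0_s = t0_s,
                 baseline = rep(1, length(values)), gain = 1, offset = 0),
            class = "corrected_trace")
}

# Fabricate a bootstrap waveform from explicit bands (for boundary cases).
fake_waveform <- function(mean, ci_lo, ci_hi, layout = snip_layout()) {
  structure(list(mean = mean, ci_lo = ci_lo, ci_hi = ci_hi,
                 time_s = (seq_along(mean) - 1) * layout$bin_s -
                   layout$pre_s,
                 n_bouts = NA_integer_, n_boot = NA_integer_,
                 alpha = 0.05, seed = NA_integer_, layout = layout),
            class = "bootstrap_waveform")
}

# Simple bout table row.
bout_row <- function(start, end, n_licks = 10L) {
  data.frame(start_s = start, end_s = end, n_licks = n_licks,
             duration_s = end - start)
}
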