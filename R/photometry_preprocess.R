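#' Construct a two-channel photometry recording
#'
#' @param ch_signal Sensor channel (465 nm excitation), numeric.
#' @param ch_control Isosbestic control channel (405 nm excitation), same
#'   length.
#' @param fs_hz Sampling rate, samples per second.
#' @param t0_s Time of the first sample, seconds.
#' @return A `photometry_recording`.
#' @export
photometry_recording <- function(ch_signal, ch_control, fs_hz, t0_s = 0) {
  if (length(ch_signal) != length(ch_control))
    stop("signal and control channels must have equal length",
         call. = FALSE)
  if (!is.numeric(fs_hz) || fs_hz <= 0)
    stop("fs_hz must be positive", call. = FALSE)
  if (any(!is.finite(ch_signal)) || any(!is.finite(ch_control)))
    stop("photometry streams must be finite", call. = FALSE)
  structure(list(fs_hz = as.numeric(fs_hz), t0_s = as.numeric(t0_s),
                 ch_signal = as.numeric(ch_signal),
                 ch_control = as.numeric(ch_control)),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d samples @ %.0f Hz (%.1f s)\n",
              length(x$ch_signal), x$fs_hz,
              length(x$ch_signal) / x$fs_hz))
  invisible(x)
}

#' Isosbestic correction of the sensor channel
#'
#' Removes components common to the sensor and control channels (slow
#' photobleaching, shared motion artifacts) while preserving
#' sensor-specific transients. Both channels are transformed to the
#' frequency domain; the control spectrum is fit to the sensor spectrum
#' over the sub-`lowpass_hz` band (a single complex-free gain plus offset),
#' the fitted control is subtracted across the full band, and the result
#' is divided by the fitted slow baseline to give fractional (dF/F-like)
#' units.
#'
#' For an input with `ch_signal = a * ch_control + b` exactly, the output
#' is zero to numerical precision; an additive transient present only in
#' the sensor channel passes through essentially unattenuated (in
#' fractional units, scaled by the local baseline, which is returned).
#'
#' @param rec A [photometry_recording()], at least 60 s long.
#' @param lowpass_hz Upper edge of the band used to fit the control to the
#'   sensor channel (default 0.05 Hz, i.e. components slower than 20 s).
#' @return A `corrected_trace`: list with `values` (fractional units),
#'   `fs_hz`, `t0_s`, `baseline` (the fitted slow baseline, raw units),
#'   `gain` and `offset` of the fit.
#' @export
correct_isosbestic <- function(rec, lowpass_hz = 0.05) {
  stopifnot(inherits(rec, "photometry_recording"))
  n <- length(rec$ch_signal)
  if (n / rec$fs_hz < 60)
    stop("insufficient data: streams must be at least 60 s long",
         call. = FALSE)
  if (stats::sd(rec$ch_control) == 0)
    stop("degenerate fit: control channel is constant", call. = FALSE)
  s <- rec$ch_signal
  ctrl <- rec$ch_control
  S <- stats::fft(s)
  C <- stats::fft(ctrl)
  f <- (seq_len(n) - 1) * rec$fs_hz / n
  f <- pmin(f, rec$fs_hz - f)              # two-sided frequency axis
  band <- f > 0 & f <= lowpass_hz
  if (!any(band))
    stop("insufficient data: no spectral bins below lowpass_hz",
         call. = FALSE)
  denom <- sum(Mod(C[band])^2)
  if (denom == 0)
    stop("degenerate fit: control has no sub-band power", call. = FALSE)
  gain <- sum(Re(S[band] * Conj(C[band]))) / denom
  offset <- (Re(S[1]) - gain * Re(C[1])) / n   # DC bins hold n * mean
  corrected <- s - (gain * ctrl + offset)
  # fitted slow baseline: gain * lowpassed control + offset
  C_lp <- C
  C_lp[!(band | f == 0)] <- 0
  ctrl_lp <- Re(stats::fft(C_lp, inverse = TRUE)) / n
  baseline <- gain * ctrl_lp + offset
  if (min(baseline) <= 0)
    stop("degenerate fit: fitted baseline is not positive", call. = FALSE)
  structure(list(values = corrected / baseline, fs_hz = rec$fs_hz,
                 t0_s = rec$t0_s, baseline = baseline, gain = gain,
                 offset = offset),
            class = "corrected_trace")
}

#' Peri-bout snip layout
#'
#' The fixed 230-bin snip grid at 0.1-s bins: 5 s baseline before the
#' bout, the first 6 s of licking, the last 2 s of licking, and 10 s
#' post-bout. Returns the per-segment bin counts and 1-based index ranges.
#'
#' @param pre_s,early_s,late_s,post_s Segment lengths in seconds.
#' @param bin_s Bin width in seconds.
#' @return A list with bin counts, index ranges and `n_bins`.
#' @export
snip_layout <- function(pre_s = 5, early_s = 6, late_s = 2, post_s = 10,
                        bin_s = 0.1) {
  lens <- c(pre_s, early_s, late_s, post_s) / bin_s
  if (any(abs(lens - round(lens)) > 1e-9))
    stop("bin_s must divide every segment length evenly", call. = FALSE)
  lens <- as.integer(round(lens))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  list(bin_s = bin_s, pre_s = pre_s, early_s = early_s, late_s = late_s,
       post_s = post_s,
       n_baseline = lens[1], n_early = lens[2], n_late = lens[3],
       n_post = lens[4], n_bins = sum(lens),
       baseline = starts[1]:ends[1], lick_early = starts[2]:ends[2],
       lick_late = starts[3]:ends[3], post = starts[4]:ends[4])
}

# Mean of trace samples within [lo, hi); falls back to linear
# interpolation at the bin center when the bin holds no sample (possible
# for time-rescaled early bins at low sampling rates).
bin_means <- function(values, fs, t0, lo, hi) {
  first <- ceiling((lo - t0) * fs + 1 - 1e-9)
  last <- ceiling((hi - t0) * fs + 1 - 1e-9) - 1
  n <- length(lo)
  out <- numeric(n)
  t_all <- NULL
  for (i in seq_len(n)) {
    if (last[i] >= first[i]) {
      out[i] <- mean(values[first[i]:last[i]])
    } else {
      if (is.null(t_all)) t_all <- t0 + (seq_along(values) - 1) / fs
      out[i] <- stats::approx(t_all, values, xout = (lo[i] + hi[i]) / 2,
                              rule = 2)$y
    }
  }
  out
}

#' Extract peri-bout snips from a corrected trace
#'
#' One snip per bout of duration at least `min_bout_s` whose full
#' pre/post windows lie inside the recording. Each snip is binned to
#' `bin_s` (mean within bin) on the fixed layout: `pre_s` baseline before
#' the first lick, the first 6 s of licking (`lick_early`), the last 2 s
#' of licking (`lick_late`), and `post_s` after the last lick. For bouts
#' of at least 8 s the early segment is the literal first 6 s; for bouts
#' between `min_bout_s` and 8 s, the licking period minus its final 2 s is
#' linearly time-rescaled onto the 60-bin early grid. Bouts too close to
#' the recording edges are skipped and counted.
#'
#' @param trace A `corrected_trace`.
#' @param bouts Bout table from [detect_bouts()].
#' @param min_bout_s Minimum bout duration to include (8 for the
#'   region-comparison analysis, 4 for the condition analysis).
#' @param pre_s,post_s,bin_s Layout parameters, see [snip_layout()].
#' @return A `snip_set`: raw binned matrix (`n_snips` x 230), the
#'   retained bout rows, artifact flags (all `FALSE` here), the layout,
#'   and counts of skipped bouts.
#' @export
extract_snips <- function(trace, bouts, min_bout_s = 8, pre_s = 5,
                          post_s = 10, bin_s = 0.1) {
  stopifnot(inherits(trace, "corrected_trace"), is.data.frame(bouts))
  lay <- snip_layout(pre_s = pre_s, post_s = post_s, bin_s = bin_s)
  fs <- trace$fs_hz
  t0 <- trace$t0_s
  t_end <- t0 + length(trace$values) / fs
  eligible <- bouts$duration_s >= min_bout_s
  n_short <- sum(!eligible)
  sel <- bouts[eligible, , drop = FALSE]
  in_range <- sel$start_s - pre_s >= t0 & sel$end_s + post_s <= t_end
  n_edge <- sum(!in_range)
  if (n_edge > 0)
    message(sprintf("extract_snips: %d bout(s) skipped at recording edges",
                    n_edge))
  sel <- sel[in_range, , drop = FALSE]
  raw <- matrix(NA_real_, nrow(sel), lay$n_bins)
  for (i in seq_len(nrow(sel))) {
    st <- sel$start_s[i]; en <- sel$end_s[i]; d <- en - st
    base_edges <- st - pre_s + bin_s * 0:lay$n_baseline
    if (d >= lay$early_s + lay$late_s) {
      early_edges <- st + bin_s * 0:lay$n_early
    } else {
      early_edges <- st + (d - lay$late_s) * (0:lay$n_early) / lay$n_early
    }
    late_edges <- (en - lay$late_s) + bin_s * 0:lay$n_late
    post_edges <- en + bin_s * 0:lay$n_post
    lo <- c(base_edges[-length(base_edges)],
            early_edges[-length(early_edges)],
            late_edges[-length(late_edges)],
            post_edges[-length(post_edges)])
    hi <- c(base_edges[-1], early_edges[-1], late_edges[-1],
            post_edges[-1])
    raw[i, ] <- bin_means(trace$values, fs, t0, lo, hi)
  }
  rownames(sel) <- NULL
  structure(list(raw = raw, z = NULL, bouts = sel,
                 artifact = rep(FALSE, nrow(sel)),
                 baseline_mean = rep(NA_real_, nrow(sel)),
                 baseline_sd = rep(NA_real_, nrow(sel)),
                 layout = lay, n_skipped_edge = n_edge,
                 n_skipped_short = n_short),
            class = "snip_set")
}

#' @export
print.snip_set <- function(x, ...) {
  cat(sprintf(
    "<snip_set> %d snips x %d bins | %d artifact | %d edge-skipped\n",
    nrow(x$raw), ncol(x$raw), sum(x$artifact), x$n_skipped_edge))
  invisible(x)
}

#' Z-score snips to their own baselines
#'
#' Each snip is normalized as `(value - baseline_mean) / baseline_sd`,
#' with mean and sample SD (n - 1 denominator) computed over that snip's
#' own baseline bins. Snips with zero baseline SD are flagged as artifacts
#' (they cannot be normalized) and logged.
#'
#' @param snips A `snip_set` from [extract_snips()].
#' @return The `snip_set` with `z`, `baseline_mean`, `baseline_sd` filled
#'   in and degenerate snips flagged.
#' @export
zscore_snips <- function(snips) {
  stopifnot(inherits(snips, "snip_set"))
  lay <- snips$layout
  n <- nrow(snips$raw)
  z <- matrix(NA_real_, n, lay$n_bins)
  bm <- bs <- numeric(n)
  flagged <- 0L
  for (i in seq_len(n)) {
    base <- snips$raw[i, lay$baseline]
    bm[i] <- mean(base)
    bs[i] <- stats::sd(base)
    if (!is.finite(bs[i]) || bs[i] == 0) {
      snips$artifact[i] <- TRUE
      flagged <- flagged + 1L
    } else {
      z[i, ] <- (snips$raw[i, ] - bm[i]) / bs[i]
    }
  }
  if (flagged > 0)
    message(sprintf(
      "zscore_snips: %d snip(s) flagged (zero baseline SD)", flagged))
  snips$z <- z
  snips$baseline_mean <- bm
  snips$baseline_sd <- bs
  snips
}

#' Artifact screen on consecutive-bin jumps
#'
#' Flags and removes snips whose maximum absolute difference between
#' consecutive binned values (pre-z-scoring, corrected units) is strictly
#' greater than `threshold`. The comparison is strict: a maximum jump
#' exactly at the threshold is kept.
#'
#' @param snips A `snip_set`.
#' @param threshold Jump threshold in corrected units (default 12).
#' @return The `snip_set` with flagged snips removed; the number removed
#'   is recorded in `n_removed_artifact` and logged.
#' @export
artifact_filter <- function(snips, threshold = 12) {
  stopifnot(inherits(snips, "snip_set"))
  if (nrow(snips$raw) == 0) {
    snips$n_removed_artifact <- 0L
    return(snips)
  }
  jumps <- apply(snips$raw, 1, function(v) max(abs(diff(v))))
  bad <- jumps > threshold | snips$artifact
  n_bad <- sum(bad)
  if (n_bad > 0)
    message(sprintf("artifact_filter: %d snip(s) removed", n_bad))
  keep <- !bad
  snips$raw <- snips$raw[keep, , drop = FALSE]
  if (!is.null(snips$z)) snips$z <- snips$z[keep, , drop = FALSE]
  snips$bouts <- snips$bouts[keep, , drop = FALSE]
  snips$artifact <- snips$artifact[keep]
  snips$baseline_mean <- snips$baseline_mean[keep]
  snips$baseline_sd <- snips$baseline_sd[keep]
  snips$n_removed_artifact <- n_bad
  snips
}

#' Combine snip sets
#'
#' Row-binds snip sets on identical layouts (e.g. snips pooled across
#' sessions or mice for the region-level waveform analysis).
#'
#' @param ... `snip_set` objects.
#' @return A single `snip_set`.
#' @export
bind_snips <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "snip_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, TRUE, "snip_set")))
  nb <- vapply(sets, function(s) s$layout$n_bins, 1L)
  if (length(unique(nb)) != 1)
    stop("snip sets must share a layout", call. = FALSE)
  out <- sets[[1]]
  out$raw <- do.call(rbind, lapply(sets, `[[`, "raw"))
  zs <- lapply(sets, `[[`, "z")
  out$z <- if (any(vapply(zs, is.null, TRUE))) NULL else do.call(rbind, zs)
  out$bouts <- do.call(rbind, lapply(sets, `[[`, "bouts"))
  rownames(out$bouts) <- NULL
  out$artifact <- unlist(lapply(sets, `[[`, "artifact"))
  out$baseline_mean <- unlist(lapply(sets, `[[`, "baseline_mean"))
  out$baseline_sd <- unlist(lapply(sets, `[[`, "baseline_sd"))
  out$n_skipped_edge <- sum(vapply(sets, `[[`, 1L, "n_skipped_edge"))
  out$n_skipped_short <- sum(vapply(sets, `[[`, 1L, "n_skipped_short"))
  out
}
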