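#' Bootstrapped peri-event waveform
#'
#' Builds the bootstrapped estimate of the mean peri-bout trace: each of
#' `n_boot` replicates resamples the snips with replacement (same size)
#' and averages per bin; the confidence band is the per-bin
#' `alpha/2`/`1 - alpha/2` percentile of the replicate means. Resampling
#' is over bout snips pooled across animals (the analysis unit), with
#' optional stratification by mouse.
#'
#' @param snips A `snip_set` with z-scores filled in (see
#'   [zscore_snips()]), or a numeric matrix with one snip per row.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param alpha Two-sided level for the confidence band (default 0.05 for
#'   a 95% band).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param stratify_by Optional factor of length `nrow` (e.g. mouse ids);
#'   when given, resampling is with replacement within each stratum.
#' @return A `bootstrap_waveform`: per-bin `mean`, `ci_lo`, `ci_hi`, the
#'   bin time axis (seconds relative to bout start), `n_bouts`, `n_boot`,
#'   `alpha`, `seed` and the snip layout.
#' @export
bootstrap_waveform <- function(snips, n_boot = 1000, alpha = 0.05,
                               seed = 1L, stratify_by = NULL) {
  if (inherits(snips, "snip_set")) {
    if (is.null(snips$z))
      stop("snips must be z-scored first (zscore_snips)", call. = FALSE)
    keep <- !snips$artifact
    x <- snips$z[keep, , drop = FALSE]
    lay <- snips$layout
  } else {
    x <- as.matrix(snips)
    lay <- snip_layout()
    if (ncol(x) != lay$n_bins)
      lay <- NULL
  }
  n <- nrow(x)
  if (n < 2)
    stop("insufficient data: need at least 2 non-artifact snips",
         call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  boot_means <- local_seed(seed, {
    if (is.null(stratify_by)) {
      idx <- sample.int(n, n * n_boot, replace = TRUE)
      # per-replicate resample counts, as an n_boot x n weight matrix
      w <- matrix(tabulate(idx + n * rep(0:(n_boot - 1), each = n),
                           nbins = n * n_boot),
                  nrow = n_boot, ncol = n, byrow = TRUE)
      (w %*% x) / n
    } else {
      stopifnot(length(stratify_by) == n)
      strata <- split(seq_len(n), stratify_by)
      w <- matrix(0, n_boot, n)
      for (s in strata) {
        ns <- length(s)
        idx <- sample(s, ns * n_boot, replace = TRUE)
        w <- w + matrix(tabulate(match(idx, seq_len(n)) +
                                   n * rep(0:(n_boot - 1), each = ns),
                                 nbins = n * n_boot),
                        nrow = n_boot, ncol = n, byrow = TRUE)
      }
      (w %*% x) / n
    }
  })
  qs <- apply(boot_means, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  bin_s <- if (!is.null(lay)) lay$bin_s else 0.1
  pre_s <- if (!is.null(lay)) lay$pre_s else 5
  structure(list(mean = colMeans(x), ci_lo = qs[1, ], ci_hi = qs[2, ],
                 time_s = (seq_len(ncol(x)) - 1) * bin_s - pre_s,
                 n_bouts = n, n_boot = n_boot, alpha = alpha,
                 seed = as.integer(seed), layout = lay),
            class = "bootstrap_waveform")
}

#' @export
print.bootstrap_waveform <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_waveform> %d bins | n_bouts=%d, n_boot=%d, alpha=%.3f\n",
    length(x$mean), x$n_bouts, x$n_boot, x$alpha))
  invisible(x)
}

# Assemble a windows table from run indices on the waveform's bin grid.
windows_from_runs <- function(runs, direction, bw) {
  bin_s <- if (!is.null(bw$layout)) bw$layout$bin_s else 0.1
  data.frame(start_bin = runs$start, end_bin = runs$end,
             start_s = bw$time_s[runs$start],
             end_s = bw$time_s[runs$end] + bin_s,
             direction = rep(direction, nrow(runs)))
}

#' Significant deviation windows of a bootstrapped waveform
#'
#' Reports maximal runs of bins where the confidence band excludes the
#' reference (band fully above: direction `"above"`; fully below:
#' `"below"`), kept only when the run spans at least `min_consecutive`
#' bins (six 0.1-s bins by default, matching the signal's low-pass
#' bandwidth). Baseline bins define the zero level and are excluded from
#' reporting by default.
#'
#' @param bw A [bootstrap_waveform()].
#' @param min_consecutive Minimum run length in bins (default 6).
#' @param reference Reference level (default 0).
#' @param exclude_baseline Exclude the baseline segment from reporting
#'   (default `TRUE`; ignored when the waveform has no layout).
#' @return A `significance_windows` data.frame: `start_bin`, `end_bin`
#'   (1-based, inclusive), `start_s`, `end_s` (window edges in seconds
#'   relative to bout start), `direction`.
#' @export
significant_windows <- function(bw, min_consecutive = 6, reference = 0,
                                exclude_baseline = TRUE) {
  stopifnot(inherits(bw, "bootstrap_waveform"))
  nb <- length(bw$mean)
  eligible <- rep(TRUE, nb)
  if (exclude_baseline && !is.null(bw$layout))
    eligible[bw$layout$baseline] <- FALSE
  out <- list()
  for (dir in c("above", "below")) {
    hit <- if (dir == "above") bw$ci_lo > reference
           else bw$ci_hi < reference
    runs <- true_runs(hit & eligible)
    runs <- runs[runs$end - runs$start + 1L >= min_consecutive, ,
                 drop = FALSE]
    if (nrow(runs)) out[[dir]] <- windows_from_runs(runs, dir, bw)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_bin = integer(0), end_bin = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               direction = character(0))
  res <- res[order(res$start_bin), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("significance_windows", "data.frame"))
}

#' Two-waveform comparison by confidence-interval overlap
#'
#' Reports maximal runs of bins where the two confidence bands are
#' disjoint (intervals touching at exactly one endpoint count as
#' overlapping), kept when at least `min_consecutive` bins long. The
#' direction labels which waveform's band lies higher over the run.
#'
#' @param a,b [bootstrap_waveform()] objects on identical bin grids.
#' @param min_consecutive Minimum run length in bins (default 6).
#' @param exclude_baseline Exclude baseline bins from reporting.
#' @return A `significance_windows` data.frame with direction
#'   `"a_greater"` or `"b_greater"`.
#' @export
compare_waveforms <- function(a, b, min_consecutive = 6,
                              exclude_baseline = TRUE) {
  stopifnot(inherits(a, "bootstrap_waveform"),
            inherits(b, "bootstrap_waveform"))
  if (length(a$mean) != length(b$mean) ||
      max(abs(a$time_s - b$time_s)) > 1e-9)
    stop("waveforms are not on identical bin grids", call. = FALSE)
  nb <- length(a$mean)
  eligible <- rep(TRUE, nb)
  if (exclude_baseline && !is.null(a$layout))
    eligible[a$layout$baseline] <- FALSE
  out <- list()
  for (dir in c("a_greater", "b_greater")) {
    hit <- if (dir == "a_greater") a$ci_lo > b$ci_hi else b$ci_lo > a$ci_hi
    runs <- true_runs(hit & eligible)
    runs <- runs[runs$end - runs$start + 1L >= min_consecutive, ,
                 drop = FALSE]
    if (nrow(runs)) out[[dir]] <- windows_from_runs(runs, dir, a)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_bin = integer(0), end_bin = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               direction = character(0))
  res <- res[order(res$start_bin), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("significance_windows", "data.frame"))
}

#' Behavior-defined epoch AUC
#'
#' Signed area of the z-scored trace over the four behavior-defined
#' epochs: early licking (first 6 s of the bout), late licking (last 2 s),
#' and the 10-s post-bout period split into two equal 5-s bins (early and
#' late post). The area is the Riemann sum of the binned trace,
#' `sum(z) * bin_s`, in z·s, so a constant z of 1 over a 5-s epoch gives
#' exactly 5.
#'
#' @param x A z-scored `snip_set` (one row of results per non-artifact
#'   snip) or a single numeric snip vector on the standard layout.
#' @param layout Layout, defaults to the snip set's own (or
#'   [snip_layout()] for a bare vector).
#' @return A data.frame with columns `early_lick`, `late_lick`,
#'   `early_post`, `late_post` (z·s).
#' @export
epoch_auc <- function(x, layout = NULL) {
  if (inherits(x, "snip_set")) {
    if (is.null(x$z))
      stop("snips must be z-scored first (zscore_snips)", call. = FALSE)
    lay <- layout %||% x$layout
    z <- x$z[!x$artifact, , drop = FALSE]
  } else {
    lay <- layout %||% snip_layout()
    z <- matrix(as.numeric(x), nrow = 1)
  }
  if (ncol(z) != lay$n_bins)
    stop("snip length does not match layout", call. = FALSE)
  half <- lay$n_post %/% 2L
  epochs <- list(early_lick = lay$lick_early, late_lick = lay$lick_late,
                 early_post = lay$post[seq_len(half)],
                 late_post = lay$post[(half + 1L):lay$n_post])
  out <- vapply(epochs, function(idx)
    rowSums(z[, idx, drop = FALSE]) * lay$bin_s, numeric(nrow(z)))
  as.data.frame(matrix(out, nrow = nrow(z),
                       dimnames = list(NULL, names(epochs))))
}
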